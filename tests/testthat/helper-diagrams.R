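# shared fixtures, built in code

# worked-example quantity sets: a published medical survey, a known-drawable
# item (region areas of a random valid ellipse triple), and a drawable item
# whose bc region is only 0.003% of the diagram
w_medical <- c(a = 0.25, b = 0.01, c = 0.11, ab = 0.10, ac = 0.29,
               bc = 0.03, abc = 0.15)
w_drawable <- c(a = 2273, b = 24458, c = 44454, ab = 7116, ac = 740,
                bc = 18807, abc = 12092)
w_thin_region <- c(a = 10018, b = 27132, c = 39737, ab = 9567, ac = 11454,
                   bc = 3, abc = 668)

# classic symmetric three-circle Venn layout
classic_venn <- function(r = 1, d = 1) {
  venn3_diagram(ellipse(0, 0, r, r),
                ellipse(d, 0, r, r),
                ellipse(d / 2, d * sqrt(3) / 2, r, r))
}

# a random diagram guaranteed to be a valid 3-Venn topology
random_valid_diagram <- function(seed) {
  random_drawable_item(seed)$diagram
}

transform_diagram <- function(d, dx = 0, dy = 0, rot = 0, scale = 1) {
  E <- unclass(d)
  cr <- cos(rot); sr <- sin(rot)
  for (i in 1:3) {
    x <- E[i, "cx"]; y <- E[i, "cy"]
    E[i, "cx"] <- scale * (cr * x - sr * y) + dx
    E[i, "cy"] <- scale * (sr * x + cr * y) + dy
    E[i, "s1"] <- E[i, "s1"] * scale
    E[i, "s2"] <- E[i, "s2"] * scale
    E[i, "theta"] <- (E[i, "theta"] + rot) %% pi
  }
  venn3_diagram(E[1, ], E[2, ], E[3, ])
}
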
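# Shared fixtures, built in code at test time.

# Noiseless linear sulfate core: surface concentration `surface` mM dropping
# to zero at `dns` cm.
linear_sulfate_profile <- function(surface = 28, dns = 25,
                                   depths = seq(1, 31, by = 2),
                                   site = "A", bay = "control",
                                   season = "summer", porosity = 0.8) {
  porewater_profile(site, bay, season, depths,
                    list(sulfate = pmax(0, surface * (1 - depths / dns))),
                    porosity)
}

# Small deterministic count table: 4 samples x 4 ASVs in 2 families.
tiny_count_table <- function() {
  counts <- matrix(c(3, 4, 0, 5,
                     1, 0, 2, 2,
                     0, 6, 1, 0,
                     7, 1, 1, 4), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("s", 1:4), paste0("asv", 1:4)))
  taxonomy <- data.frame(asv_id = paste0("asv", 1:4),
                         domain = "Bacteria", phylum = "P", class = "C",
                         order = "O",
                         family = c("FamA", "FamA", "FamB", "FamB"),
                         stringsAsFactors = FALSE)
  metadata <- data.frame(sample_id = paste0("s", 1:4),
                         site = "x",
                         bay = c("control", "control", "heated", "heated"),
                         season = "summer", depth_cm = c(1, 10, 1, 10),
                         stringsAsFactors = FALSE)
  count_table(counts, taxonomy, metadata)
}

# Classical two-group pseudo-F computed directly from squared distances
# (within/between decomposition), independent of the hat-matrix route.
two_group_pseudo_f <- function(d, labels) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  ss_total <- sum(D2) / (2 * n)
  ss_within <- sum(vapply(unique(labels), function(g) {
    idx <- labels == g
    sum(D2[idx, idx]) / (2 * sum(idx))
  }, numeric(1)))
  ((ss_total - ss_within) / (length(unique(labels)) - 1)) /
    (ss_within / (n - length(unique(labels))))
}
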
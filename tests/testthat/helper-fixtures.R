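# Rasterized disk fixtures used across segmentation tests.

disk_mask <- function(n, centers, r) {
  m <- matrix(0, n, n)
  xs <- seq_len(n)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt(outer((xs - centers[i, 1])^2, (xs - centers[i, 2])^2, `+`))
    m[d <= r] <- 1
  }
  m
}

# Two disks with centers `sep_radii` radii apart (overlapping when < 2).
two_disk_mask <- function(n = 128, r = 20, sep_radii = 1.2) {
  d <- sep_radii * r
  disk_mask(n, rbind(c(n / 2 - d / 2, n / 2), c(n / 2 + d / 2, n / 2)), r)
}

random_substrate <- function() {
  substrate_mechanics(E_star = 10^stats::runif(1, 4, 9),
                      delta_gamma = 10^stats::runif(1, -2, 1.5),
                      R = 10^stats::runif(1, -8, -6))
}
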
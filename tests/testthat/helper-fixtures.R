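# shared fixtures, all generated in code

# binary disk mask centred in a square frame
disk_mask <- function(r, pad = 10) {
  side <- 2 * r + 2 * pad + 1
  ctr <- r + pad + 1
  g <- expand.grid(row = seq_len(side), col = seq_len(side))
  matrix((g$row - ctr)^2 + (g$col - ctr)^2 <= r^2 + r, side, side)
}

# two disks joined by a thin bridge, as an 8-bit image (dark fibers on a
# bright background, like a boundary-stained section)
bridged_disks_image <- function(r = 30, gap = 40, bridge_halfwidth = 1) {
  side <- 2 * r + 60
  width <- 4 * r + gap + 60
  m <- matrix(FALSE, side, width)
  c1 <- c(side / 2, r + 30)
  c2 <- c(side / 2, 3 * r + gap + 30)
  g <- expand.grid(row = seq_len(side), col = seq_len(width))
  m[(g$row - c1[1])^2 + (g$col - c1[2])^2 <= r^2 + r] <- TRUE
  m[(g$row - c2[1])^2 + (g$col - c2[2])^2 <= r^2 + r] <- TRUE
  rows <- round(side / 2) + (-bridge_halfwidth:bridge_halfwidth)
  m[rows, seq(c1[2], c2[2])] <- TRUE
  image_grid(matrix(ifelse(m, 0, 255), side, width), 8L)
}

# brute-force BH adjustment straight from the definition
bh_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  sorted <- p[ord] * m / seq_len(m)
  q[ord] <- rev(cummin(rev(sorted)))
  pmin(q, 1)
}

expect_tibble <- function(x) expect_s3_class(x, "tbl_df")
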
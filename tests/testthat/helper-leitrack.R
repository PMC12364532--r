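# Fixture builders shared across the suite. Everything is generated in
# code; nothing is read from stored binary data.

# rasterize a filled rotated ellipse by direct point inclusion -- kept
# deliberately separate from the package renderer so shape tests have an
# independent drawing path
rasterEllipse <- function(H, W, cr, cc, a, b, phiDeg = 0) {
  phi <- phiDeg * pi / 180
  x <- matrix(rep(seq_len(W) - cc, each = H), H, W)
  y <- matrix(rep(-(seq_len(H) - cr), W), H, W)
  u <- x * cos(phi) + y * sin(phi)
  v <- -x * sin(phi) + y * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

rasterDisc <- function(H, W, cr, cc, R)
  rasterEllipse(H, W, cr, cc, R, R)

# brute-force double-loop moment oracle
naiveMoments <- function(mask) {
  n <- 0; sr <- 0; sc <- 0
  for (r in seq_len(nrow(mask))) for (cl in seq_len(ncol(mask)))
    if (mask[r, cl]) { n <- n + 1; sr <- sr + r; sc <- sc + cl }
  rbar <- sr / n; cbar <- sc / n
  m20 <- 0; m02 <- 0; m11 <- 0
  for (r in seq_len(nrow(mask))) for (cl in seq_len(ncol(mask)))
    if (mask[r, cl]) {
      m20 <- m20 + (r - rbar)^2
      m02 <- m02 + (cl - cbar)^2
      m11 <- m11 + (r - rbar) * (cl - cbar)
    }
  list(n = n, centroid = c(rbar, cbar),
       mu20 = m20 / n, mu02 = m02 / n, mu11 = m11 / n)
}

# a flat green-on-dark RGB frame from a logical mask
frameFromMask <- function(mask, plant = c(0.1, 0.8, 0.1),
                          bg = c(0.05, 0.05, 0.05),
                          meta = FrameMeta("fix", "top", 0)) {
  px <- array(rep(bg, each = length(mask)), dim = c(dim(mask), 3))
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[mask] <- plant[ch]
    px[, , ch] <- plane
  }
  Frame(px, meta = meta)
}

# write a tiny valid green PNG frame under the filename convention
writeTinyFrame <- function(dir, plant, view, minutes, H = 16, W = 16) {
  m <- matrix(FALSE, H, W); m[5:12, 5:12] <- TRUE
  f <- frameFromMask(m)
  path <- file.path(dir, sprintf("%s_%s_%04d.png", plant, view, minutes))
  png::writePNG(framePixels(f), path)
  path
}

# angle difference modulo 180 degrees (ellipse orientations are axial)
axialDiffDeg <- function(a, b) {
  d <- abs(a - b) %% 180
  min(d, 180 - d)
}
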
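# Independent oracles and small fixture builders shared across tests.

# Brute-force dip decision: explicit neighbour-comparison peak finding
# and a per-sample scan of the 50% rule, written independently of the
# package's classifier.
oracleDipDecision <- function(profile, background, dipThreshold = 0.5) {
  b <- profile - background
  b[b < 0] <- 0
  n <- length(b)
  peaks <- c()
  for (i in seq_len(n)) {
    left <- i == 1 || b[i] > b[i - 1]
    right <- i == n || b[i] > b[i + 1]
    if (left && right && b[i] > 0) peaks <- c(peaks, i)
  }
  if (length(peaks) < 2) return("abnormal")
  i1 <- peaks[1]; i2 <- peaks[length(peaks)]
  ref <- min(b[i1], b[i2])
  for (j in i1:i2) {
    if (b[j] <= dipThreshold * ref) return("out")
  }
  "not_out"
}

# Random two-bump profile with a guaranteed two-peak structure.
randomTwoPeakProfile <- function(n, bg) {
  x <- seq_len(n)
  p1 <- sample(2:max(2, floor(n / 3)), 1)
  p2 <- sample(min(n - 1, ceiling(2 * n / 3)):(n - 1), 1)
  h1 <- runif(1, 50, 300); h2 <- runif(1, 50, 300)
  w1 <- runif(1, 1, n / 6); w2 <- runif(1, 1, n / 6)
  bg + h1 * exp(-(x - p1)^2 / (2 * w1^2)) +
    h2 * exp(-(x - p2)^2 / (2 * w2^2))
}

# Textbook step-up rule at budget Q, written as an explicit loop.
oracleStepUp <- function(p, Q) {
  m <- length(p)
  sp <- sort(p)
  kmax <- 0
  for (i in seq_len(m)) {
    if (sp[i] < (i / m) * Q) kmax <- i
  }
  if (kmax == 0) return(rep(FALSE, m))
  thr <- sp[kmax]
  p <= thr
}

# Draw a filled disk into a matrix (1-based centre, radius in px).
drawDisk <- function(img, center, radius, value = 1) {
  for (r in seq_len(nrow(img))) {
    for (c in seq_len(ncol(img))) {
      if ((r - center[1])^2 + (c - center[2])^2 <= radius^2)
        img[r, c] <- value
    }
  }
  img
}

makeBlob <- function(pixels) {
  pixels <- matrix(pixels, ncol = 2)
  list(pixels = pixels, centroid = colMeans(pixels),
       areaPx = nrow(pixels), peak = 1, isDot = TRUE)
}

voxelDiagonal <- function(pixelSizeXY = 0.054, sectionThicknessZ = 0.5) {
  sqrt(2 * pixelSizeXY^2 + sectionThicknessZ^2)
}
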
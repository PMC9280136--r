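# shared test helpers: independent oracles kept deliberately naive

# row-major 3x3 constructor for readable fixtures
m3 <- function(...) matrix(c(...), 3, 3, byrow = TRUE)

fro <- function(m) sqrt(sum(m^2))

# a Haar-ish random orthogonal 3x3 (QR of a Gaussian matrix)
random_orthogonal <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# flatten a 3x3 matrix the way triple_magnitudes() expects
flat9 <- function(g) c(g)

# naive 26-connectivity flood fill on a logical 3D array; returns an
# integer label array (0 = background), labels in discovery order
flood_fill_oracle <- function(bin) {
  d <- dim(bin)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  nxt <- 0L
  for (start in which(bin)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      i <- queue[1]
      queue <- queue[-1]
      co <- arrayInd(i, d)
      for (r in seq_len(nrow(nb))) {
        p <- co + nb[r, ]
        if (any(p < 1) || any(p > d)) next
        j <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
        if (bin[j] && lab[j] == 0L) {
          lab[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  lab
}

# modality_fields object with prescribed value arrays, for averaging and
# labeling tests that need exact control over node values
fake_modalities <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                            defined = NULL, time = 0) {
  d <- dim(values)
  if (is.null(defined)) defined <- !is.na(values)
  structure(list(strain = values, rotation = values, shear = values,
                 sss = values, defined = defined, dims = as.integer(d),
                 spacing = spacing, origin = origin, time = time),
            class = "modality_fields")
}
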
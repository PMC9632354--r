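# fixtures shared across test files; all generated in code

# canonical open-eye landmark set: corners (0,0)/(4,0), lid pairs at +-1
open_eye <- rbind(p1 = c(0, 0), p2 = c(1, 1), p3 = c(1, -1),
                  p4 = c(3, 1), p5 = c(3, -1), p6 = c(4, 0))

# mouth with corners (0,0)/(4,0); verticals 2, 3, 2 px
open_mouth <- rbind(m1 = c(0, 0), m2 = c(1, 1), m3 = c(2, 1.5),
                    m4 = c(3, 1), m5 = c(4, 0), m6 = c(3, -1),
                    m7 = c(2, -1.5), m8 = c(1, -1))

random_boxes <- function(n, lim = 50) {
  x1 <- runif(n, 0, lim); y1 <- runif(n, 0, lim)
  data.frame(x1 = x1, y1 = y1,
             x2 = x1 + runif(n, 0.5, lim / 2),
             y2 = y1 + runif(n, 0.5, lim / 2),
             score = runif(n))
}

rigid_transform <- function(pts, angle = 0, scale = 1, shift = c(0, 0)) {
  r <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  sweep(scale * pts %*% t(r), 2, -shift)
}

# brute-force Nadaraya-Watson oracle, written independently of grnn_predict
nw_oracle <- function(patterns, labels, sigma, query) {
  w <- numeric(nrow(patterns))
  for (i in seq_len(nrow(patterns)))
    w[i] <- exp(-sum((query - patterns[i, ])^2) / (2 * sigma^2))
  sum(labels * w) / sum(w)
}

# brute-force leave-one-out MSE oracle
loo_oracle <- function(patterns, labels, sigma) {
  n <- nrow(patterns)
  preds <- numeric(n)
  for (i in seq_len(n))
    preds[i] <- nw_oracle(patterns[-i, , drop = FALSE], labels[-i], sigma,
                          patterns[i, ])
  mean((preds - labels)^2)
}

# small fast profile for session-level tests
test_profile <- function(...) subject_profile(...)
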
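# Shared fixtures, built in code.

# Hard-edged disk image: `inside` within radius r of (cx, cy), else `outside`.
makeDisk <- function(cx, cy, r, h = 120, w = 120, inside = 0.1, outside = 0.9) {
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  Y <- matrix(seq_len(h), h, w)
  ifelse(sqrt((X - cx)^2 + (Y - cy)^2) <= r, inside, outside)
}

# Two concentric hard edges: pupil disk inside an iris disk inside sclera.
makeTwoEdge <- function(cx = 112, cy = 112, rp = 20, ri = 60, h = 224, w = 224,
                        vals = c(0.1, 0.45, 0.85)) {
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  Y <- matrix(seq_len(h), h, w)
  rho <- sqrt((X - cx)^2 + (Y - cy)^2)
  out <- matrix(vals[3], h, w)
  out[rho <= ri] <- vals[2]
  out[rho <= rp] <- vals[1]
  out
}

# Paint a hard bright disk onto an image (interference spot).
paintSpot <- function(img, cx, cy, r, value = 0.99) {
  h <- nrow(img); w <- ncol(img)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  Y <- matrix(seq_len(h), h, w)
  img[sqrt((X - cx)^2 + (Y - cy)^2) <= r] <- value
  img
}

cleanSpec <- function(seed = 1L, ...) SceneSpec(seed = as.integer(seed),
                                                blurSigma = 0.5, ...)
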
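# Independent oracles used by the tests; deliberately implemented without
# reference to the package's own algorithms.

# Brute-force isochromat Bloch simulation of a CPMG multi-echo spin-echo
# train with explicit crusher dephasing (n_iso spins spread uniformly over
# 2 pi per half echo spacing), instantaneous rotations, and relaxation.
bloch_mese_oracle <- function(t2, t1, b1, esp, n_echoes, refocus_deg,
                              n_iso = 201) {
  th <- 2 * pi * (seq_len(n_iso) - 0.5) / n_iso
  rotx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  roty <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  E2 <- exp(-esp / 2 / t2); E1 <- exp(-esp / 2 / t1)
  M <- matrix(0, 3, n_iso); M[3, ] <- 1
  M <- roty(b1 * pi / 2) %*% M
  half <- function(M) {
    M[1, ] <- M[1, ] * E2; M[2, ] <- M[2, ] * E2
    M[3, ] <- M[3, ] * E1 + (1 - E1)
    x <- M[1, ] * cos(th) - M[2, ] * sin(th)
    y <- M[1, ] * sin(th) + M[2, ] * cos(th)
    M[1, ] <- x; M[2, ] <- y
    M
  }
  aref <- b1 * refocus_deg * pi / 180
  out <- numeric(n_echoes)
  for (e in seq_len(n_echoes)) {
    M <- half(M)
    M <- rotx(aref) %*% M
    M <- half(M)
    out[e] <- Mod(mean(M[1, ] + 1i * M[2, ]))
  }
  out
}

# Repeated 6-connected erosion.
erode_k <- function(mask, k) {
  for (i in seq_len(k)) mask <- multiqmap:::erode6(mask)
  mask
}
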
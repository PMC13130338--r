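# Shared fixture builders: everything is generated in code, nothing on disk.

# random non-degenerate k x 2 configuration
rand_config <- function(k = 16L, sd = 1) {
  matrix(stats::rnorm(2L * k, sd = sd), k, 2L)
}

# apply a similarity transform (rotation, positive scale, translation)
apply_similarity <- function(m, angle, scale = 1, trans = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  sweep(scale * m %*% t(R), 2L, trans, "+")
}

# independent SVD-based oracle for the Riemann distance (no reflection):
# cos(rho) = s1 + sign(det) * s2 of M = t(P1) %*% P2 on the preshapes
rho_svd_oracle <- function(a, b) {
  p1 <- preshape(a); p2 <- preshape(b)
  M <- t(p1) %*% p2
  s <- svd(M)$d
  acos(min(1, s[1L] + sign(det(M)) * s[2L]))
}

# small TPS-format text fixture written to a temp file
write_tps_text <- function(lines) {
  path <- tempfile(fileext = ".tps")
  writeLines(lines, path)
  path
}

# quick two-group synthetic pair from one population spec
sim_pair <- function(spec) {
  list(a = simulate_sample(spec, 1L), b = simulate_sample(spec, 2L))
}
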
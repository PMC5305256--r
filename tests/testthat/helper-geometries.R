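# Worked-geometry fixtures for the interaction criteria: residue pairs
# whose group distances and donor-H-acceptor angle are set exactly.
leu_pair <- function(com_dist) {
  side <- rbind(c(0.05, 0, 0), c(-0.05, 0, 0), c(0, 0.05, 0), c(0, -0.05, 0))
  nm <- c("CB", "CG", "CD1", "CD2")
  two_residue_model("LEU", nm, sweep(side, 2, c(0, -0.5, 0), `+`),
                    "LEU", nm, sweep(side, 2, c(com_dist, -0.5, 0), `+`))
}

hbond_model <- function(da_dist, dha_angle) {
  # donor OG at origin-side, H 0.1 nm along +x, acceptor placed so that
  # |D-A| = da_dist and the D-H-A angle equals dha_angle (degrees)
  D <- c(0, -0.5, 0)
  H <- D + c(0.1, 0, 0)
  u <- c(-1, 0, 0)                      # H -> D direction
  th <- dha_angle * pi / 180
  v <- cos(th) * u + sin(th) * c(0, 1, 0)  # H -> A direction
  # solve |H + t v - D| = da_dist for t > 0
  w <- H - D
  t <- max(Re(polyroot(c(sum(w^2) - da_dist^2, 2 * sum(w * v), 1))))
  A <- H + t * v
  stopifnot(abs(sqrt(sum((A - D)^2)) - da_dist) < 1e-9)
  two_residue_model("SER", c("OG", "HG"), rbind(D, H),
                    "GLU", "OE1", matrix(A, nrow = 1))
}

salt_model <- function(com_dist) {
  two_residue_model("LYS", "NZ", matrix(c(0, -0.5, 0), nrow = 1),
                    "GLU", c("CD", "OE1", "OE2"),
                    local({
                      g <- rbind(c(-0.065, 0, 0), c(0.06, 0.06, 0), c(0.06, -0.06, 0))
                      m <- c(12.011, 15.999, 15.999)
                      com <- colSums(g * m) / sum(m)
                      sweep(g, 2, c(com_dist, -0.5, 0) - com, `+`)
                    }))
}
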
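# small builders shared across test files

makeTraj <- function(positions, dt = 15, id = "c1", condition = "unspecified",
                     replicate = "R1") {
  positions <- as.matrix(positions)
  Trajectory(id, times = dt * (seq_len(nrow(positions)) - 1),
             positions = positions, condition = condition,
             replicate = replicate)
}

# rotate a position matrix by `deg` degrees about the origin
rotatePositions <- function(p, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p %*% t(R)
}

# random fuzzed walk matrix: n positions with N(0, scale) steps
fuzzWalk <- function(n, scale = 2) {
  apply(matrix(stats::rnorm(2 * n, 0, scale), n, 2), 2, cumsum)
}

# walk params for a flow-oriented (wild-type-like) cell
biasOnParams <- function(...) {
  WalkParams(biasStrength = 0.3, targetMode = "fixed_direction",
             target = c(-1, 0), turnSd = 0.6, ...)
}
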
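# Independent oracle for superposition RMSD: hierarchical brute-force grid
# search over rotations (ZYZ Euler angles), refining around the best cell.
# Never touches the package's Kabsch path.
gridRmsd <- function(P, Q) {
  rotZ <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                            c(0, 0, 1))
  rotY <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                            c(-sin(a), 0, cos(a)))
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  val <- function(a, b, c) {
    D <- Pc %*% (rotZ(a) %*% rotY(b) %*% rotZ(c)) - Qc
    sqrt(mean(rowSums(D^2)))
  }
  ctr <- c(0, 0, 0)
  width <- pi
  best <- Inf
  for (lvl in 1:6) {
    grid <- seq(-width, width, length.out = 11L)
    for (a in ctr[1] + grid) for (b in ctr[2] + grid) {
      for (cc in ctr[3] + grid) {
        v <- val(a, b, cc)
        if (v < best) {
          best <- v
          found <- c(a, b, cc)
        }
      }
    }
    ctr <- found
    width <- width / 5
  }
  best
}
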
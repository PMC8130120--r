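# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately coded as naive brute-force versions, separate from the package
# implementations they check.

# fast SASA parameters for pipeline tests (accuracy tests set their own)
fast_sasa <- function(n_points = 240) sasa_params(n_points = n_points)

# hand-built structure model from an atom data frame (hs_structure layout)
fake_model <- function(atoms, chain_kinds) {
  structure(list(atoms = atoms, chain_kinds = chain_kinds, source = "fake"),
            class = "hs_structure")
}

atom_row <- function(serial, name, resname, chain, resseq, x, y, z, element) {
  data.frame(het = FALSE, serial = serial, name = name, altloc = " ",
             resname = resname, chain = chain, resseq = resseq, icode = "",
             x = x, y = y, z = z, occupancy = 1, element = element,
             stringsAsFactors = FALSE)
}

toy_model <- function(gap = 3.5, seed = 1, ...) {
  txt <- make_toy_complex(gap = gap, seed = seed, ...)
  read_pdb(paste(txt, collapse = "\n"))
}

# ---- independent oracles -------------------------------------------------

# Eq.-style one-liner INP oracles
oracle_inp1 <- function(tm, tc, nm, nc) tm / mean(nm) - tc / mean(nc)
oracle_inp2 <- function(t, nb) t / mean(nb)

# dihedral via projection onto the plane perpendicular to the central bond;
# sign convention frozen against an external reference (+90 for the
# quadruple below, verified with biotite's structure.dihedral)
oracle_dihedral <- function(a, b, c, d) {
  b2 <- c - b
  u <- (a - b) - sum((a - b) * b2) / sum(b2 * b2) * b2
  w <- (d - c) - sum((d - c) * b2) / sum(b2 * b2) * b2
  cr <- c(u[2] * w[3] - u[3] * w[2],
          u[3] * w[1] - u[1] * w[3],
          u[1] * w[2] - u[2] * w[1])
  atan2(sum(cr * b2 / sqrt(sum(b2^2))), sum(u * w)) * 180 / pi
}

# O(n^2) pair-counting AUC with half credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# brute-force half-sphere contact counting
oracle_hse <- function(ca, cb, others, radius) {
  axis <- (cb - ca) / sqrt(sum((cb - ca)^2))
  up <- down <- 0
  for (i in seq_len(nrow(others))) {
    v <- as.numeric(others[i, ]) - ca
    if (sqrt(sum(v^2)) > radius) next
    if (sum(v * axis) >= 0) up <- up + 1 else down <- down + 1
  }
  c(up = up, down = down, total = up + down)
}

# Reference SVM dual solution via quadprog (oracle for the SMO solver).
# The dual Hessian is singular for low-rank kernels, so a small ridge keeps
# solve.QP's factorization honest (without it the returned point can violate
# the box constraints); the solution must be box-feasible to count.
oracle_svm_dual <- function(K, y, C, ridge = 1e-4) {
  n <- length(y)
  D <- (y %*% t(y)) * K + diag(ridge, n)
  A <- cbind(y, diag(n), -diag(n))
  b0 <- c(0, rep(0, n), rep(-C, n))
  sol <- quadprog::solve.QP(D, rep(1, n), A, b0, meq = 1)
  alpha <- sol$solution
  stopifnot(min(alpha) > -1e-6, max(alpha) < C + 1e-6)
  obj <- 0.5 * drop(t(alpha * y) %*% K %*% (alpha * y)) - sum(alpha)
  list(alpha = alpha, objective = obj)
}
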
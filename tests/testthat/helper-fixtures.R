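# Shared fixtures and independent oracles for the test suite.

# Minimal chain built from explicit atom placements: `residues` is a list of
# lists with fields name3, seq_number, and an atoms matrix (rows = x,y,z)
# with optional rownames as atom names.
chain_from_atoms <- function(residues, chain_id = "A", pdb_id = "FIXT",
                             resolution = 1.5, r_free = 0.20, r_work = 0.18) {
  rows <- list()
  for (i in seq_along(residues)) {
    r <- residues[[i]]
    m <- r$atoms
    nm <- rownames(m)
    if (is.null(nm)) nm <- paste0("C", seq_len(nrow(m)))
    rows[[i]] <- data.frame(
      res_index = i - 1L,
      seq_number = if (is.null(r$seq_number)) i else r$seq_number,
      icode = "", name3 = r$name3, atom = nm,
      element = substr(nm, 1, 1), x = m[, 1], y = m[, 2], z = m[, 3],
      occupancy = 1, altloc = "", is_heavy = TRUE,
      stringsAsFactors = FALSE)
  }
  chain_model(do.call(rbind, rows), pdb_id = pdb_id, chain_id = chain_id,
              resolution = resolution, r_free = r_free, r_work = r_work)
}

# Single-atom residues at given CA-like positions (name3 recycled).
point_chain <- function(positions, name3 = "ALA") {
  residues <- lapply(seq_len(nrow(positions)), function(i) {
    m <- positions[i, , drop = FALSE]
    rownames(m) <- "CA"
    list(name3 = name3[(i - 1) %% length(name3) + 1], atoms = m)
  })
  chain_from_atoms(residues)
}

# O(N^2) brute-force contact oracle: double loop over all heavy-atom pairs.
brute_force_contacts <- function(chain, cutoff = 4.5,
                                 min_seq_separation = 2) {
  a <- chain$atoms[chain$atoms$is_heavy, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  counts <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(a))) {
      if (j <= i) next
      ri <- a$res_index[i]; rj <- a$res_index[j]
      if (abs(ri - rj) < min_seq_separation) next
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) {
        key <- paste(min(ri, rj), max(ri, rj))
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  if (!length(counts)) {
    return(data.frame(res_a = integer(0), res_b = integer(0),
                      atom_pair_count = integer(0)))
  }
  ks <- strsplit(names(counts), " ")
  out <- data.frame(
    res_a = as.integer(vapply(ks, `[`, "", 1)),
    res_b = as.integer(vapply(ks, `[`, "", 2)),
    atom_pair_count = as.integer(unlist(counts)))
  out[order(out$res_a, out$res_b), , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random symmetric weighted adjacency on n nodes with edge probability p.
random_adjacency <- function(n, p = 0.4, seed = 1) {
  set.seed(seed)
  a <- matrix(0, n, n)
  up <- upper.tri(a)
  on_edge <- up & matrix(runif(n * n) < p, n, n)
  a[on_edge] <- runif(sum(on_edge), 0.05, 1)
  a <- a + t(a)
  dimnames(a) <- list(paste0("p", 1:n), paste0("p", 1:n))
  a
}

random_psn <- function(n, p = 0.4, seed = 1, hub_threshold = 11) {
  a <- random_adjacency(n, p, seed)
  nodes <- data.frame(node = rownames(a), res_index = seq_len(n) - 1L,
                      seq_number = seq_len(n), icode = "",
                      name3 = "ALA", stringsAsFactors = FALSE)
  psndelta:::new_psn(nodes, a, hub_threshold = hub_threshold)
}

# PSN from an explicit adjacency matrix (labels p1..pn).
psn_from_adjacency <- function(a, hub_threshold = 11) {
  n <- nrow(a)
  dimnames(a) <- list(paste0("p", 1:n), paste0("p", 1:n))
  nodes <- data.frame(node = rownames(a), res_index = seq_len(n) - 1L,
                      seq_number = seq_len(n), icode = "",
                      name3 = "ALA", stringsAsFactors = FALSE)
  psndelta:::new_psn(nodes, a, hub_threshold = hub_threshold)
}

# Independent Needleman-Wunsch/Gotoh affine-gap global alignment oracle.
# Returns 0-based index pairs of aligned (non-gap) columns.
gotoh_align <- function(s1, s2, gap_open = 10, gap_extend = 0.5) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  sub <- BLOSUM62
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 2) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - (j - 2) * gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open, X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open, Y[i, j - 1] - gap_extend)
    }
  }
  # traceback
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  pairs <- NULL
  while (i > 1 || j > 1) {
    if (state == 1) {
      pairs <- rbind(c(i - 2, j - 2), pairs)
      s <- sub[a[i - 1], b[j - 1]]
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      state <- which.max(ifelse(abs(prev - M[i, j]) < 1e-9, prev, NEG))
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      from_m <- abs(M[i - 1, j] - gap_open - X[i, j]) < 1e-9
      i <- i - 1
      state <- if (from_m) 1 else 2
    } else {
      from_m <- abs(M[i, j - 1] - gap_open - Y[i, j]) < 1e-9
      j <- j - 1
      state <- if (from_m) 1 else 3
    }
  }
  pairs
}

# Numerical superposition oracle: minimize RMSD over rotations (Euler
# angles) and translations with multi-start Nelder-Mead.
rmsd_minimizer_oracle <- function(A, B) {
  rotmat <- function(e) {
    cx <- cos(e[1]); sx <- sin(e[1]); cy <- cos(e[2]); sy <- sin(e[2])
    cz <- cos(e[3]); sz <- sin(e[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(par) {
    R <- rotmat(par[1:3])
    moved <- sweep(B %*% t(R), 2, par[4:6], "+")
    sqrt(mean(rowSums((A - moved)^2)))
  }
  best <- Inf
  set.seed(42)
  for (s in 1:25) {
    start <- c(runif(3, -pi, pi), colMeans(A) - colMeans(B))
    r <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-12))
    r <- optim(r$par, obj, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-14))
    best <- min(best, r$value)
  }
  best
}

# Exhaustive optimal eigenvector assignment oracle: over all permutations,
# pick the pairing maximizing total |cosine|.
exhaustive_matching <- function(spec_a, spec_b) {
  n <- spec_a$n
  M <- abs(crossprod(spec_a$vectors, spec_b$vectors))
  perms <- gtools_permutations(n)
  best <- -Inf; best_p <- NULL
  for (k in seq_len(nrow(perms))) {
    p <- perms[k, ]
    tot <- sum(M[cbind(seq_len(n), p)])
    if (tot > best + 1e-12) { best <- tot; best_p <- p }
  }
  data.frame(rank_a = seq_len(n), rank_b = best_p,
             abs_cos = pmin(M[cbind(seq_len(n), best_p)], 1))
}

gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Direct-summation CRS/EWCS oracles from a given pairing.
crs_direct <- function(matching, n) {
  1 - 6 * sum((matching$rank_a - matching$rank_b)^2) / (n * (n^2 - 1))
}
ewcs_direct <- function(spec_a, spec_b, matching) {
  w <- abs(1 - spec_a$values[matching$rank_a]) *
    abs(1 - spec_b$values[matching$rank_b])
  if (sum(w) == 0) return(0)
  sqrt(sum(w * (1 - matching$abs_cos)^2) / sum(w))
}

# A handcrafted 3-residue, 12-atom PDB fixture (fixed-column text).
handcrafted_pdb <- function(path) {
  lines <- c(
    "REMARK   2 RESOLUTION.    2.50 ANGSTROMS.",
    "REMARK   3   R VALUE            (WORKING SET) : 0.210",
    "REMARK   3   FREE R VALUE                     : 0.250",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.300   2.400   0.000  1.00  0.00           O",
    "ATOM      5  N   GLY A   2       3.300   1.500   0.000  1.00  0.00           N",
    "ATOM      6  CA  GLY A   2       4.000   2.800   0.000  1.00  0.00           C",
    "ATOM      7  C   GLY A   2       5.500   2.700   0.000  1.00  0.00           C",
    "ATOM      8  O   GLY A   2       6.100   1.600   0.000  1.00  0.00           O",
    "ATOM      9  N   SER A   3       6.200   3.800   0.000  1.00  0.00           N",
    "ATOM     10  CA  SER A   3       7.650   3.900   0.000  1.00  0.00           C",
    "ATOM     11  C   SER A   3       8.200   5.300   0.000  1.00  0.00           C",
    "ATOM     12  OG  SER A   3       8.400   3.000   1.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}
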
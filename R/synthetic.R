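# Synthetic structure pairs with controlled perturbation regimes.
#
# An idealized alpha-helical backbone carries pseudo-side-chains with the
# correct heavy-atom count per residue type, stacked along the outward
# radial from each C-alpha. Two perturbation regimes bracket the behaviours
# seen in real wildtype/mutant pairs: side-chain repacking (backbone fixed,
# network altered) and hinge bending (backbone moved, local networks
# preserved). The PSN depends only on atom positions and counts, so the
# simplified geometry exercises every code path without rotamer libraries.

# run code under a Mersenne-Twister seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

.helix_point <- function(t, radius = 2.3, rise = 1.5, turn_deg = 100) {
  ang <- t * turn_deg * pi / 180
  cbind(radius * cos(ang), radius * sin(ang), t * rise)
}

# side-chain atom names (generic carbon pseudo-atoms, up to TRP's 10)
.sc_names <- c("CB", "CG", "CD", "CE", "CZ", "CH", "CI", "CJ", "CK", "CL")

# Side-chain growth direction: the outward radial tilted alternately up and
# down the helix axis with period 4, so side chains one helical turn apart
# (sequence separation 4) interdigitate. A purely radial direction cannot
# produce any contact at separation >= 2 on this idealized helix (the rise
# alone exceeds the cut-off), which would leave the network edgeless.
.sc_direction <- function(i, ca) {
  radial <- c(ca[1], ca[2], 0) / sqrt(ca[1]^2 + ca[2]^2)
  s <- if (floor(i / 4) %% 2 == 0) 1 else -1
  d <- radial + c(0, 0, 1.2 * s)
  d / sqrt(sum(d^2))
}

.build_residue_atoms <- function(i, name1, jitter_fun) {
  # i is the 0-based residue index; backbone on the helical curve
  name3 <- aa_one_to_three(name1)
  n_sc <- .aa()$n_sidechain_heavy[match(name3, .aa()$name3)]
  ca <- .helix_point(i)
  nn <- .helix_point(i - 0.33)
  cc <- .helix_point(i + 0.33)
  radial <- c(ca[1], ca[2], 0) / sqrt(ca[1]^2 + ca[2]^2)
  oo <- cc + 1.23 * radial
  atoms <- rbind(nn, ca, cc, oo)
  names_out <- c("N", "CA", "C", "O")
  elements <- c("N", "C", "C", "O")
  if (n_sc > 0) {
    d <- .sc_direction(i, ca)
    for (k in seq_len(n_sc)) {
      pos <- ca + (1.5 * k) * d + jitter_fun()
      atoms <- rbind(atoms, pos)
      names_out <- c(names_out, .sc_names[k])
      elements <- c(elements, "C")
    }
  }
  data.frame(res_index = i, seq_number = i + 1L, icode = "", name3 = name3,
             atom = names_out, element = elements,
             x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
             occupancy = 1, altloc = "", is_heavy = TRUE,
             stringsAsFactors = FALSE)
}

#' Generate an idealized helical chain
#'
#' Builds an alpha-helical backbone (rise 1.5 A, 100 degrees per residue,
#' radius 2.3 A) with N, CA, C, O backbone atoms and pseudo-side-chain
#' carbon atoms — one per heavy side-chain atom of the residue type —
#' stacked outward along the radial from the C-alpha at 1.5 A spacing with
#' seeded jitter of norm at most 0.3 A. Fully deterministic per seed.
#'
#' @param n_res number of residues (>= 10 recommended for a non-trivial
#'   network).
#' @param sequence one-letter sequence of length `n_res`; defaults to
#'   poly-alanine.
#' @param seed integer seed.
#' @param pdb_id,chain_id identifiers recorded on the chain.
#' @return a `chain_model`.
#' @export
make_chain <- function(n_res, sequence = strrep("A", n_res), seed = 1,
                       pdb_id = "SYNT", chain_id = "A") {
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  if (length(letters1) != n_res)
    stop("sequence length differs from n_res")
  if (anyNA(match(letters1, .aa()$name1)))
    stop("non-standard residue letter in sequence: ",
         paste(unique(letters1[is.na(match(letters1, .aa()$name1))]),
               collapse = ", "))
  with_seed(seed, {
    jitter_fun <- function() {
      v <- stats::rnorm(3)
      v / sqrt(sum(v^2)) * stats::runif(1, 0, 0.3)
    }
    atoms <- do.call(rbind, lapply(seq_len(n_res) - 1L, function(i)
      .build_residue_atoms(i, letters1[i + 1L], jitter_fun)))
    chain_model(atoms, pdb_id = pdb_id, chain_id = chain_id,
                resolution = 1.5, r_free = 0.20, r_work = 0.18)
  })
}

.backbone_names <- c("N", "CA", "C", "O")

#' Displace side-chain atoms of a random residue subset
#'
#' Backbone atoms (N, CA, C, O) are bitwise unchanged; each side-chain
#' pseudo-atom of the selected residues is displaced by a random vector of
#' norm at most `magnitude`. Emulates side-chain repacking: zero C-alpha
#' RMSD with an altered contact network.
#'
#' @param chain a `chain_model`.
#' @param fraction fraction of residues to perturb, in [0, 1].
#' @param magnitude maximum displacement in Angstrom.
#' @param seed integer seed.
#' @return a perturbed `chain_model`.
#' @export
perturb_sidechains <- function(chain, fraction, magnitude, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1, magnitude >= 0)
  if (fraction == 0 || magnitude == 0) return(chain)
  with_seed(seed, {
    n <- n_residues(chain)
    chosen <- sort(sample.int(n, round(fraction * n))) - 1L
    atoms <- chain$atoms
    sel <- which(atoms$res_index %in% chosen &
                   !(atoms$atom %in% .backbone_names))
    for (k in sel) {
      v <- stats::rnorm(3)
      v <- v / sqrt(sum(v^2)) * stats::runif(1, 0, magnitude)
      atoms$x[k] <- atoms$x[k] + v[1]
      atoms$y[k] <- atoms$y[k] + v[2]
      atoms$z[k] <- atoms$z[k] + v[3]
    }
    out <- chain
    out$atoms <- atoms
    out
  })
}

#' Rigid hinge-bend of the chain tail
#'
#' Rotates all atoms of residues after the pivot rigidly by `angle` degrees
#' about an axis through the pivot C-alpha perpendicular to the helix axis
#' (the tangential direction at the pivot, so a positive angle swings the
#' tail outward, away from the body of the helix, without steric overlap).
#' Pairwise distances within each segment are preserved exactly; emulates a
#' backbone conformational change with preserved local networks.
#'
#' @param chain a `chain_model`.
#' @param pivot 0-based residue index, strictly inside the chain.
#' @param angle rotation in degrees.
#' @return a bent `chain_model`.
#' @export
hinge_bend <- function(chain, pivot, angle) {
  n <- n_residues(chain)
  if (!(pivot > 0 && pivot < n - 1)) stop("pivot out of range")
  if (angle == 0) return(chain)
  atoms <- chain$atoms
  ca <- atoms[atoms$res_index == pivot & atoms$atom == "CA", , drop = FALSE]
  center <- c(ca$x[1], ca$y[1], ca$z[1])
  radial <- c(center[1], center[2], 0)
  radial <- radial / sqrt(sum(radial^2))
  axis <- c(-radial[2], radial[1], 0)
  th <- angle * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sel <- atoms$res_index > pivot
  xyz <- as.matrix(atoms[sel, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, center) %*% t(R), 2, center, "+")
  atoms[sel, c("x", "y", "z")] <- xyz
  out <- chain
  out$atoms <- atoms
  out
}

#' Substitute one residue's type
#'
#' Replaces the side chain at `position` with a freshly built pseudo-side
#' chain of the target type (atom count from the residue-type table, seeded
#' jitter); backbone atoms unchanged.
#'
#' @param chain a `chain_model`.
#' @param position 0-based residue index.
#' @param target one-letter code of the new residue type.
#' @param seed integer seed for the new side chain's jitter.
#' @return a mutated `chain_model`.
#' @export
mutate_residue <- function(chain, position, target, seed = 1) {
  n <- n_residues(chain)
  if (position < 0 || position >= n) stop("position out of range")
  name3 <- aa_one_to_three(target)
  if (is.na(name3)) stop("non-standard residue letter: ", target)
  with_seed(seed, {
    jitter_fun <- function() {
      v <- stats::rnorm(3)
      v / sqrt(sum(v^2)) * stats::runif(1, 0, 0.3)
    }
    atoms <- chain$atoms
    res_atoms <- atoms[atoms$res_index == position, , drop = FALSE]
    keep <- atoms$res_index != position
    bb <- res_atoms[res_atoms$atom %in% .backbone_names, , drop = FALSE]
    bb$name3 <- name3
    ca <- bb[bb$atom == "CA", , drop = FALSE]
    d <- .sc_direction(position, c(ca$x[1], ca$y[1], ca$z[1]))
    n_sc <- .aa()$n_sidechain_heavy[match(name3, .aa()$name3)]
    sc <- NULL
    if (n_sc > 0) {
      sc <- do.call(rbind, lapply(seq_len(n_sc), function(k) {
        pos <- c(ca$x[1], ca$y[1], ca$z[1]) + 1.5 * k * d + jitter_fun()
        data.frame(res_index = position, seq_number = ca$seq_number[1],
                   icode = "", name3 = name3, atom = .sc_names[k],
                   element = "C", x = pos[1], y = pos[2], z = pos[3],
                   occupancy = 1, altloc = "", is_heavy = TRUE,
                   stringsAsFactors = FALSE)
      }))
    }
    new_atoms <- rbind(atoms[keep, , drop = FALSE], bb, sc)
    new_atoms <- new_atoms[order(new_atoms$res_index), , drop = FALSE]
    rownames(new_atoms) <- NULL
    chain_model(new_atoms, pdb_id = chain$pdb_id, chain_id = chain$chain_id,
                resolution = chain$resolution, r_free = chain$r_free,
                r_work = chain$r_work)
  })
}

#' Scenario constructor for synthetic structure pairs
#'
#' @param name one of `"identity"`, `"sidechain_repack"`, `"hinge_bend"`,
#'   `"point_mutation"`.
#' @param n_res residues per chain (default 80, a small single-domain
#'   size giving networks large enough for stable spectra).
#' @param seed integer seed determining sequence, geometry and perturbation.
#' @param parameters scenario-specific overrides: `fraction` and
#'   `magnitude` (repack, defaults 0.5 / 3.0 A), `pivot` and `angle`
#'   (hinge, defaults 3n/4 / 60 degrees), `position` and `target`
#'   (mutation, defaults n/2 / "W").
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(name = c("identity", "sidechain_repack",
                                        "hinge_bend", "point_mutation"),
                               n_res = 80, seed = 1, parameters = list()) {
  name <- match.arg(name)
  if (n_res < 10) stop("n_res must be at least 10")
  defaults <- switch(
    name,
    identity = list(),
    sidechain_repack = list(fraction = 0.5, magnitude = 3.0),
    hinge_bend = list(pivot = floor(3 * n_res / 4), angle = 60),
    point_mutation = list(position = floor(n_res / 2), target = "W"))
  structure(list(name = name, n_res = n_res, seed = seed,
                 parameters = utils::modifyList(defaults, parameters)),
            class = "synthetic_scenario")
}

#' Generate a wildtype-like / mutant-like chain pair
#'
#' Builds the scenario's reference chain (random mixed sequence from the
#' seed) and its perturbed partner, and records the qualitative signature
#' the scenario must show: whether C-alpha RMSD and NDS are zero, and
#' whether lost/gained edge classes may be non-empty.
#'
#' @param scenario a `synthetic_scenario` (or a scenario name, passed to
#'   [synthetic_scenario()]).
#' @param ... forwarded to [synthetic_scenario()] when `scenario` is a name.
#' @return list with `wt`, `mut` (`chain_model`s), `scenario`, and
#'   `expected` (list `rmsd_zero`, `nds_zero`, `partitions_empty`).
#' @export
make_pair <- function(scenario, ...) {
  if (is.character(scenario)) scenario <- synthetic_scenario(scenario, ...)
  if (!inherits(scenario, "synthetic_scenario"))
    stop("unknown scenario")
  seq_chars <- with_seed(scenario$seed,
                         sample(.aa()$name1, scenario$n_res, replace = TRUE))
  wt <- make_chain(scenario$n_res, paste(seq_chars, collapse = ""),
                   seed = scenario$seed)
  p <- scenario$parameters
  mut <- switch(
    scenario$name,
    identity = wt,
    sidechain_repack = perturb_sidechains(wt, p$fraction, p$magnitude,
                                          seed = scenario$seed + 1000L),
    hinge_bend = hinge_bend(wt, p$pivot, p$angle),
    point_mutation = mutate_residue(wt, p$position, p$target,
                                    seed = scenario$seed + 2000L))
  expected <- switch(
    scenario$name,
    identity = list(rmsd_zero = TRUE, nds_zero = TRUE,
                    partitions_empty = TRUE),
    sidechain_repack = list(rmsd_zero = TRUE, nds_zero = FALSE,
                            partitions_empty = FALSE),
    hinge_bend = list(rmsd_zero = FALSE, nds_zero = NA,
                      partitions_empty = NA),
    point_mutation = list(rmsd_zero = TRUE, nds_zero = NA,
                          partitions_empty = NA))
  list(wt = wt, mut = mut, scenario = scenario, expected = expected)
}

#' Default synthetic fixture chain set
#'
#' Ten helical chains with seeded random sequences and lengths between 30
#' and 60 residues; the set behind the bundled default normalization table.
#'
#' @param n number of chains (default 10).
#' @param base_seed seed offset.
#' @return list of `chain_model`.
#' @export
fixture_chains <- function(n = 10, base_seed = 100) {
  lapply(seq_len(n), function(k) {
    seed <- base_seed + k
    len <- with_seed(seed, sample(30:60, 1))
    seq_chars <- with_seed(seed + 1,
                           paste(sample(.aa()$name1, len, replace = TRUE),
                                 collapse = ""))
    make_chain(len, seq_chars, seed = seed,
               pdb_id = sprintf("SYN%02d", k))
  })
}
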
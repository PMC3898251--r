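## Deterministic generators of ideal-geometry test structures with known
## ground truth, so every stage of the pipeline can be validated offline.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

elem_of <- function(elety) {
  known <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C", SG = "S",
             OXT = "O")
  out <- unname(known[elety])
  out[is.na(out)] <- guess_element(elety[is.na(out)])
  out
}

#' Specification of a planted disulfide bridge
#'
#' Describes one synthetic test structure: two cysteines realizing exact
#' requested side-chain torsions, embedded in extended alanine flanks.
#'
#' @param chi3 Planted disulfide torsion CB-SG-SG'-CB', degrees.
#' @param chi1_a,chi1_b Planted chi1 torsions, degrees.
#' @param flank_len Alanine residues on each side of each cysteine.
#' @param noise_sigma Standard deviation of i.i.d. Gaussian noise added to
#'   every coordinate, Angstrom.
#' @param seed Seed used when `noise_sigma > 0`.
#' @param bfactor_plan `"constant"` (all atoms B = 10) or `"gradient"`
#'   (residue means rise linearly 5 to 50 along the chain).
#' @return An object of class `bridge_spec`.
#' @export
#' @examples
#' bridge_spec(chi3 = 97, chi1_a = 180)
bridge_spec <- function(chi3 = -87, chi1_a = -60, chi1_b = -60,
                        flank_len = 3, noise_sigma = 0, seed = 1,
                        bfactor_plan = c("constant", "gradient")) {
  bfactor_plan <- match.arg(bfactor_plan)
  stopifnot(is.numeric(chi3), is.numeric(chi1_a), is.numeric(chi1_b),
            flank_len >= 0, noise_sigma >= 0)
  structure(list(chi3 = chi3, chi1_a = chi1_a, chi1_b = chi1_b,
                 flank_len = as.integer(flank_len),
                 noise_sigma = noise_sigma, seed = seed,
                 bfactor_plan = bfactor_plan),
            class = "bridge_spec")
}

#' Ideal-geometry residue template
#'
#' Backbone (N, CA, C, O) plus CB built with standard internal coordinates
#' and L-amino-acid chirality, CA at the origin. Used as the flank template
#' and as a hand-checkable input in tests.
#'
#' @param params An [ideal_params()] object.
#' @return Named list of 3-vector coordinates (N, CA, C, O, CB).
#' @export
ideal_residue <- function(params = ideal_params()) {
  n <- c(1.458, 0, 0)
  ca <- c(0, 0, 0)
  c_ <- 1.525 * c(cos(deg2rad(111)), sin(deg2rad(111)), 0)
  o <- place_atom(n, ca, c_, 1.231, 120.5, 0)
  cb <- construct_cbeta(n, ca, c_, params)
  list(N = n, CA = ca, C = c_, O = o, CB = cb)
}

atom_rows <- function(coords, resid, chain, resno, b) {
  elety <- names(coords)
  m <- do.call(rbind, coords)
  data.frame(elety = elety, resid = resid, chain = chain,
             resno = as.integer(resno), insert = "",
             x = m[, 1L], y = m[, 2L], z = m[, 3L],
             o = 1.0, b = b, elesy = elem_of(elety),
             reskey = res_key(chain, resno, ""),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Exact inverse kinematics of one cystine: both cysteines realize the
# requested chi1/chi1'/chi3 with ideal bond lengths and angles. chi2-like
# torsions about the CB-SG bonds are free parameters of the pose and are
# fixed at typical native values.
build_bridge_atoms <- function(spec, ideal, chi2_a = -86, chi2_b = -75) {
  n_a <- c(1.458, 0, 0)
  ca_a <- c(0, 0, 0)
  c_a <- 1.525 * c(cos(deg2rad(111)), sin(deg2rad(111)), 0)
  o_a <- place_atom(n_a, ca_a, c_a, 1.231, 120.5, 0)
  cb_a <- construct_cbeta(n_a, ca_a, c_a, ideal)
  sg_a <- place_sgamma(n_a, ca_a, cb_a, spec$chi1_a, ideal)
  sg_b <- place_atom(ca_a, cb_a, sg_a, ideal$d_ss, ideal$ang_cb_s_s, chi2_a)
  cb_b <- place_atom(cb_a, sg_a, sg_b, ideal$d_cb_sg, ideal$ang_cb_s_s,
                     spec$chi3)
  ca_b <- place_atom(sg_a, sg_b, cb_b, ideal$d_ca_cb, ideal$ang_ca_cb_sg,
                     chi2_b)
  n_b <- place_atom(sg_b, cb_b, ca_b, 1.458, 110.5, spec$chi1_b)
  # C must sit on the L-chirality side of the N/CB pair
  c_b <- NULL
  for (delta in c(122.5, -122.5)) {
    cand <- place_atom(sg_b, cb_b, ca_b, 1.525, 110.5, spec$chi1_b + delta)
    if (dihedral(n_b, ca_b, cand, cb_b) < 0) { c_b <- cand; break }
  }
  o_b <- place_atom(n_b, ca_b, c_b, 1.231, 120.5, 0)
  list(a = list(N = n_a, CA = ca_a, C = c_a, O = o_a, CB = cb_a, SG = sg_a),
       b = list(N = n_b, CA = ca_b, C = c_b, O = o_b, CB = cb_b, SG = sg_b))
}

#' Build a synthetic structure containing one ideal disulfide bridge
#'
#' Constructs two cysteines whose side chains realize exactly the requested
#' chi1, chi1' and chi3 torsions with ideal covalent geometry (S-S bond
#' length `ideal$d_ss`, both CB-SG-SG' angles at `ideal$ang_cb_s_s`),
#' embedded in extended alanine flanks kept more than 6 Angstrom away from
#' the sulfurs so they cannot produce additional candidates. An SSBOND
#' record marks the planted pair. Optional Gaussian coordinate noise is
#' seeded and reproducible.
#'
#' @param spec A [bridge_spec()].
#' @param ideal An [ideal_params()] object.
#' @return A list with components `model` (an `ss_model`) and `truth`
#'   (planted angles, SG/CB coordinates, and the residue keys of the pair).
#' @export
#' @examples
#' fx <- build_ideal_bridge(bridge_spec(chi3 = 97))
#' fx$truth$chi3
build_ideal_bridge <- function(spec, ideal = ideal_params()) {
  stopifnot(inherits(spec, "bridge_spec"))
  br <- build_bridge_atoms(spec, ideal)
  f <- spec$flank_len
  no_a <- f + 1L          # cysteine A residue number
  no_b <- f + 3L          # cysteine B: sequence separation 2
  tmpl <- ideal_residue(ideal)

  mid <- (br$a$SG + br$b$SG) / 2
  dir_a <- unitv(br$a$CA - mid, "flank direction")
  dir_b <- unitv(br$b$CA - mid, "flank direction")

  blocks <- list()
  add_flank <- function(k, center_ca, dir, resno) {
    shift <- center_ca + (4 + 7 * k) * dir
    coords <- lapply(tmpl, function(p) p + shift)
    atom_rows(coords, "ALA", "A", resno, 10)
  }
  if (f > 0L) for (k in f:1L)   # residues 1..f approach cysteine A
    blocks[[length(blocks) + 1L]] <- add_flank(k, br$a$CA, dir_a, f + 1L - k)
  blocks[[length(blocks) + 1L]] <- atom_rows(br$a, "CYS", "A", no_a, 10)
  blocks[[length(blocks) + 1L]] <- atom_rows(br$b, "CYS", "A", no_b, 10)
  if (f > 0L) for (k in 1L:f)
    blocks[[length(blocks) + 1L]] <- add_flank(k, br$b$CA, dir_b, no_b + k)
  atoms <- do.call(rbind, blocks)
  rownames(atoms) <- NULL

  if (spec$bfactor_plan == "gradient") {
    keys <- unique(atoms$reskey)
    bres <- if (length(keys) == 1L) 5
            else 5 + 45 * (seq_along(keys) - 1L) / (length(keys) - 1L)
    atoms$b <- bres[match(atoms$reskey, keys)]
  }
  if (spec$noise_sigma > 0) {
    atoms[, c("x", "y", "z")] <- with_seed(spec$seed, {
      atoms[, c("x", "y", "z")] +
        matrix(stats::rnorm(3L * nrow(atoms), 0, spec$noise_sigma),
               ncol = 3L)
    })
  }

  ssb <- data.frame(chain1 = "A", resno1 = no_a, insert1 = "",
                    chain2 = "A", resno2 = no_b, insert2 = "",
                    stringsAsFactors = FALSE)
  model <- new_ss_model(1L, atoms, ssb, "synthetic-bridge")
  truth <- list(key_a = res_key("A", no_a), key_b = res_key("A", no_b),
                res_a = no_a, res_b = no_b,
                chi1_a = spec$chi1_a, chi1_b = spec$chi1_b, chi3 = spec$chi3,
                theta_a = ideal$ang_cb_s_s, theta_b = ideal$ang_cb_s_s,
                sg_a = br$a$SG, sg_b = br$b$SG,
                cb_a = br$a$CB, cb_b = br$b$CB)
  list(model = model, truth = truth)
}

#' Build a multi-model PDB stream of noised bridge copies
#'
#' Each MODEL block is an independently noised copy of the same planted
#' bridge (the noise seed is offset by the model index), mimicking an NMR
#' ensemble. With `noise_sigma = 0` all models are identical.
#'
#' @param n_models Number of MODEL blocks (>= 1).
#' @param spec A [bridge_spec()].
#' @param ideal An [ideal_params()] object.
#' @return PDB-format text (character vector of lines).
#' @export
build_multimodel <- function(n_models, spec, ideal = ideal_params()) {
  if (!is.numeric(n_models) || length(n_models) != 1L || n_models < 1)
    stop("n_models must be a single integer >= 1", call. = FALSE)
  n_models <- as.integer(n_models)
  models <- lapply(seq_len(n_models), function(k) {
    sk <- spec
    sk$seed <- spec$seed + k
    m <- build_ideal_bridge(sk, ideal)$model
    m$model_id <- k
    m
  })
  write_pdb(models)
}

#' Build a synthetic survey set of planted bridges
#'
#' Draws `n` bridges with chi3 uniform on \[-92, -82\] or \[+92, +102\]
#' (each half with probability 1/2) and chi1 torsions sampled from the
#' canonical rotamers \{-60, 60, 180\}, all at exact ideal geometry
#' (no coordinate noise). Serves as the in-package stand-in for a survey of
#' native disulfide-containing structures, with fully known ground truth.
#'
#' @param n Number of structures (>= 1).
#' @param seed Seed for the draws.
#' @param flank_len Alanine flank length passed to [bridge_spec()].
#' @param ideal An [ideal_params()] object.
#' @return A list of `n` elements, each as returned by
#'   [build_ideal_bridge()].
#' @export
#' @examples
#' set <- build_survey_set(5, seed = 7)
#' sapply(set, function(s) s$truth$chi3)
build_survey_set <- function(n, seed = 7, flank_len = 3,
                             ideal = ideal_params()) {
  stopifnot(n >= 1)
  draws <- with_seed(seed, {
    data.frame(
      chi3 = ifelse(stats::runif(n) < 0.5,
                    stats::runif(n, -92, -82),
                    stats::runif(n, 92, 102)),
      chi1_a = sample(c(-60, 60, 180), n, replace = TRUE),
      chi1_b = sample(c(-60, 60, 180), n, replace = TRUE))
  })
  lapply(seq_len(n), function(i) {
    fx <- build_ideal_bridge(
      bridge_spec(chi3 = draws$chi3[i], chi1_a = draws$chi1_a[i],
                  chi1_b = draws$chi1_b[i], flank_len = flank_len),
      ideal)
    fx$model$source_id <- sprintf("synthetic-%03d", i)
    fx
  })
}
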
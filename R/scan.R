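#' Geometric scan configuration
#'
#' Tolerances and search settings for the disulfide scan. The stringency
#' parameters are deliberately user-adjustable: the defaults admit
#' near-native geometry generously (chi3 within 10 degrees of either native
#' cluster, S-S bond length within 0.2 Angstrom of ideal, CB-SG-SG' angles
#' within 10 degrees of ideal) and can be tightened or relaxed per project.
#'
#' @param chi3_windows Accepted chi3 windows: a list of `c(center,
#'   tolerance)` pairs, degrees.
#' @param ss_bond_tolerance Maximum deviation of the modeled S-S distance
#'   from the ideal bond length, Angstrom.
#' @param angle_tolerance Maximum deviation of each CB-SG-SG' angle from
#'   ideal, degrees.
#' @param cb_cb_range Admissible CB-CB distance interval `c(low, high)`,
#'   Angstrom; pairs outside it are rejected before pose search.
#' @param chi1_grid_step Coarse chi1 x chi1' grid spacing, degrees; must
#'   divide 360.
#' @param refine Locally refine the best grid poses (coordinate descent to
#'   a step below 0.01 degrees)?
#' @param min_seq_separation Minimum |residue number| separation for
#'   same-chain pairs; inter-chain pairs are always allowed.
#' @param include_native_cys Scan residues that are already cysteine?
#'   Predictions on native disulfide pairs are flagged `is_native`.
#' @param energy_cutoff Optional maximum total energy, kcal/mol; `NULL`
#'   keeps every geometrically valid candidate.
#' @param use_file_cb Use the file's CB coordinates when present instead of
#'   rebuilding CB from the backbone? Off by default so predictions use
#'   backbone geometry only, making glycine and missing-atom cases uniform
#'   (the file CB is still used for B-factor averaging).
#' @return An object of class `scan_config`.
#' @export
#' @examples
#' scan_config(chi3_windows = list(c(-87, 30), c(97, 30)))
scan_config <- function(chi3_windows = list(c(-87, 10), c(97, 10)),
                        ss_bond_tolerance = 0.2,
                        angle_tolerance = 10,
                        cb_cb_range = c(3.0, 5.5),
                        chi1_grid_step = 5,
                        refine = TRUE,
                        min_seq_separation = 2,
                        include_native_cys = TRUE,
                        energy_cutoff = NULL,
                        use_file_cb = FALSE) {
  if (!is.list(chi3_windows) || length(chi3_windows) == 0L ||
      !all(vapply(chi3_windows, function(w)
        is.numeric(w) && length(w) == 2L && w[2L] >= 0, logical(1L))))
    stop("chi3_windows must be a non-empty list of c(center, tolerance >= 0)")
  if (ss_bond_tolerance < 0 || angle_tolerance < 0)
    stop("tolerances must be >= 0")
  if (length(cb_cb_range) != 2L || cb_cb_range[1L] >= cb_cb_range[2L])
    stop("cb_cb_range must be c(low, high) with low < high")
  if (chi1_grid_step <= 0 || abs(360 / chi1_grid_step -
                                 round(360 / chi1_grid_step)) > 1e-9)
    stop("chi1_grid_step must be positive and divide 360")
  if (min_seq_separation < 1) stop("min_seq_separation must be >= 1")
  if (!is.null(energy_cutoff) && (!is.numeric(energy_cutoff) ||
                                  length(energy_cutoff) != 1L))
    stop("energy_cutoff must be NULL or a single number")
  structure(list(chi3_windows = chi3_windows,
                 ss_bond_tolerance = ss_bond_tolerance,
                 angle_tolerance = angle_tolerance,
                 cb_cb_range = cb_cb_range,
                 chi1_grid_step = chi1_grid_step,
                 refine = isTRUE(refine),
                 min_seq_separation = as.integer(min_seq_separation),
                 include_native_cys = isTRUE(include_native_cys),
                 energy_cutoff = energy_cutoff,
                 use_file_cb = isTRUE(use_file_cb)),
            class = "scan_config")
}

ang_diff <- function(a, b) ((a - b + 180) %% 360) - 180

residue_mean_bfactor <- function(atoms) {
  sel <- atoms$elety %in% c("N", "CA", "C", "O", "CB")
  if (!any(sel)) return(NA_real_)
  mean(atoms$b[sel])
}

#' Summed pair B-factor (the Sigma-B metric)
#'
#' The mobility metric used to rank candidate bridges by expected
#' stabilization: each residue contributes the arithmetic mean B-factor of
#' its backbone (N, CA, C, O) and beta-carbon atoms that are present
#' (glycine: backbone only), and the two per-residue means are summed.
#'
#' @param model An `ss_model`.
#' @param key_a,key_b Residue keys (as in `model$atom$reskey`).
#' @return The Sigma-B value in Angstrom squared.
#' @export
pair_sum_bfactor <- function(model, key_a, key_b) {
  out <- vapply(c(key_a, key_b), function(k) {
    a <- model$atom[model$atom$reskey == k, , drop = FALSE]
    if (nrow(a) == 0L) stop("residue ", k, " not found in model", call. = FALSE)
    residue_mean_bfactor(a)
  }, numeric(1L))
  if (any(is.na(out)))
    stop("undefined B-factor: residue has none of N, CA, C, O, CB",
         call. = FALSE)
  sum(out)
}

# Per-residue side-chain frame: SG(chi1) = base + A*cos(chi1) + B*sin(chi1).
sg_frame <- function(n, ca, cb, params) {
  b1 <- ca - n; b2 <- cb - ca
  u2 <- unitv(b2, "CA->CB bond")
  nz <- unitv(cross3(b1, b2), "side-chain frame")
  m <- cross3(nz, u2)
  th <- deg2rad(params$ang_ca_cb_sg)
  r <- params$d_cb_sg
  list(base = cb - r * cos(th) * u2, A = r * sin(th) * m, B = r * sin(th) * nz)
}

sg_at <- function(frame, chi_deg) {
  ph <- deg2rad(chi_deg)
  frame$base + frame$A * cos(ph) + frame$B * sin(ph)
}

sg_grid <- function(frame, grid_deg) {
  ph <- deg2rad(grid_deg)
  cbind(frame$base[1L] + frame$A[1L] * cos(ph) + frame$B[1L] * sin(ph),
        frame$base[2L] + frame$A[2L] * cos(ph) + frame$B[2L] * sin(ph),
        frame$base[3L] + frame$A[3L] * cos(ph) + frame$B[3L] * sin(ph))
}

# Build the per-residue geometry table used by the scan. Residues lacking
# a complete backbone are skipped with a single summary warning.
scan_residues <- function(model, config, ideal) {
  atoms <- model$atom
  keys <- unique(atoms$reskey)
  idx <- split(seq_len(nrow(atoms)), factor(atoms$reskey, levels = keys))
  skipped <- character()
  out <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    a <- atoms[idx[[i]], , drop = FALSE]
    need <- c("N", "CA", "C")
    if (!all(need %in% a$elety)) {
      skipped <- c(skipped, keys[i])
      next
    }
    g <- function(e) as.numeric(a[match(e, a$elety), c("x", "y", "z")])
    n <- g("N"); ca <- g("CA"); c_ <- g("C")
    cb <- if (config$use_file_cb && "CB" %in% a$elety) g("CB")
          else tryCatch(construct_cbeta(n, ca, c_, ideal),
                        error = function(e) NULL)
    if (is.null(cb)) { skipped <- c(skipped, keys[i]); next }
    out[[i]] <- list(key = keys[i], chain = a$chain[1L], resno = a$resno[1L],
                     insert = a$insert[1L], aa = a$resid[1L],
                     n = n, ca = ca, cb = cb,
                     mean_b = residue_mean_bfactor(a))
  }
  if (length(skipped) > 0L)
    warning("skipped ", length(skipped),
            " residue(s) with incomplete or degenerate backbone: ",
            paste(utils::head(skipped, 5L), collapse = ", "),
            if (length(skipped) > 5L) ", ..." else "", call. = FALSE)
  out[!vapply(out, is.null, logical(1L))]
}

# Pattern-search refinement of |d(SG_a, SG_b) - d_ss| over (chi_a, chi_b).
refine_pose <- function(fa, fb, chi_a, chi_b, step0, d_ss, tol_step = 0.005) {
  dev <- function(pa, pb) abs(vnorm(sg_at(fa, pa) - sg_at(fb, pb)) - d_ss)
  best <- dev(chi_a, chi_b)
  step <- step0
  while (step >= tol_step) {
    improved <- FALSE
    for (mv in list(c(step, 0), c(-step, 0), c(0, step), c(0, -step))) {
      cand <- dev(chi_a + mv[1L], chi_b + mv[2L])
      if (cand < best - 1e-13) {
        chi_a <- chi_a + mv[1L]; chi_b <- chi_b + mv[2L]
        best <- cand
        improved <- TRUE
      }
    }
    if (!improved) step <- step / 2
  }
  c(chi_a = wrap_angle(chi_a), chi_b = wrap_angle(chi_b), dev = best)
}

wrap_angle <- function(a) {
  out <- ((a + 180) %% 360) - 180
  out[out <= -180] <- out[out <= -180] + 360
  out
}

# Periodic local minima of a matrix (TRUE where an entry is <= all four
# wrap-around neighbours).
periodic_local_min <- function(m) {
  n <- nrow(m); k <- ncol(m)
  up <- m[c(n, seq_len(n - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(n - 1L) + 1L, 1L), , drop = FALSE]
  lf <- m[, c(k, seq_len(k - 1L)), drop = FALSE]
  rt <- m[, c(seq_len(k - 1L) + 1L, 1L), drop = FALSE]
  m <= up & m <= dn & m <= lf & m <= rt
}

#' Scan a structure for candidate disulfide bridges
#'
#' The core predictor. For every residue pair at sequence separation of at
#' least `config$min_seq_separation` (inter-chain pairs always allowed):
#' the beta carbons are rebuilt from backbone coordinates; pairs whose
#' CB-CB distance falls outside `config$cb_cb_range` are rejected; cysteine
#' sulfurs are modeled on both residues over a chi1 x chi1' grid and the
#' poses bringing the S-S distance nearest the ideal bond length are
#' locally refined; poses are kept only if the S-S deviation is within
#' `ss_bond_tolerance`, chi3 falls inside a configured window, and both
#' CB-SG-SG' angles are within `angle_tolerance` of ideal. Among surviving
#' poses for a pair the one with the lowest total energy is reported (ties
#' broken by proximity of chi3 to a window center, then by chi1 of the
#' first residue). Native cysteine pairs present in the file's SSBOND
#' records are flagged `is_native`. Only backbone and beta-carbon geometry
#' is consulted, never the file's sulfur positions, so native disulfides
#' are predicted blind.
#'
#' @param model An `ss_model` from [read_pdb()] or the fixture generators.
#' @param config A [scan_config()].
#' @param energy An [energy_params()] object.
#' @param ideal An [ideal_params()] object.
#' @param progress Optional callback, called with the fraction of residue
#'   pairs processed (roughly once per percent).
#' @return A data frame of class `ss_predictions`, one row per predicted
#'   bridge, ordered by (chain, residue) of the pair: residue identities,
#'   the modeled `chi1_a`, `chi1_b`, `chi3`, `theta_a`, `theta_b` angles
#'   (degrees), the modeled S-S distance (Angstrom), the energy and its
#'   per-term breakdown (kcal/mol), the Sigma-B mobility metric, the
#'   modeled SG coordinates, and the `is_native` flag.
#' @export
#' @examples
#' fx <- build_ideal_bridge(bridge_spec())
#' scan_disulfides(fx$model)[, c("res1", "res2", "chi3", "energy")]
scan_disulfides <- function(model, config = scan_config(),
                            energy = energy_params(),
                            ideal = ideal_params(),
                            progress = NULL) {
  stopifnot(inherits(model, "ss_model"), inherits(config, "scan_config"))
  res <- scan_residues(model, config, ideal)
  if (config$include_native_cys == FALSE)
    res <- res[vapply(res, function(r) r$aa != "CYS", logical(1L))]
  nres <- length(res)
  if (nres < 2L)
    stop("nothing to scan: fewer than 2 usable residues", call. = FALSE)

  step <- config$chi1_grid_step
  grid <- seq(-180 + step, 180, by = step)
  frames <- lapply(res, function(r) sg_frame(r$n, r$ca, r$cb, ideal))
  grids <- lapply(frames, sg_grid, grid_deg = grid)

  cbm <- t(vapply(res, function(r) r$cb, numeric(3L)))
  cb2 <- rowSums(cbm^2)
  dcb <- sqrt(pmax(outer(cb2, cb2, "+") - 2 * tcrossprod(cbm), 0))

  chains <- vapply(res, function(r) r$chain, "")
  resnos <- vapply(res, function(r) r$resno, 1L)
  pairs <- which(upper.tri(dcb), arr.ind = TRUE)
  sep_ok <- chains[pairs[, 1L]] != chains[pairs[, 2L]] |
    abs(resnos[pairs[, 1L]] - resnos[pairs[, 2L]]) >= config$min_seq_separation
  pairs <- pairs[sep_ok, , drop = FALSE]
  n_pairs <- nrow(pairs)

  # native pair lookup
  nat <- model$ssbonds
  nat_keys <- if (nrow(nat) > 0L) {
    k1 <- res_key(nat$chain1, nat$resno1, nat$insert1)
    k2 <- res_key(nat$chain2, nat$resno2, nat$insert2)
    paste(pmin(k1, k2), pmax(k1, k2))
  } else character()

  # SG displacement bound for half a grid step, both sulfurs
  r_perp <- ideal$d_cb_sg * sin(deg2rad(ideal$ang_ca_cb_sg))
  slack <- if (config$refine) 4 * r_perp * sin(deg2rad(step) / 4) else 0

  tick <- max(1L, floor(n_pairs / 100))
  preds <- list()
  for (pi in seq_len(n_pairs)) {
    if (!is.null(progress) && pi %% tick == 0L) progress(pi / n_pairs)
    i <- pairs[pi, 1L]; j <- pairs[pi, 2L]
    if (dcb[i, j] < config$cb_cb_range[1L] ||
        dcb[i, j] > config$cb_cb_range[2L]) next

    ga <- grids[[i]]; gb <- grids[[j]]
    d2 <- outer(rowSums(ga^2), rowSums(gb^2), "+") - 2 * tcrossprod(ga, gb)
    devm <- abs(sqrt(pmax(d2, 0)) - ideal$d_ss)
    cand <- which(periodic_local_min(devm) &
                    devm <= config$ss_bond_tolerance + slack,
                  arr.ind = TRUE)
    if (nrow(cand) == 0L) next

    poses <- matrix(NA_real_, nrow(cand), 3L)
    for (ci in seq_len(nrow(cand))) {
      pa <- grid[cand[ci, 1L]]; pb <- grid[cand[ci, 2L]]
      poses[ci, ] <- if (config$refine)
        refine_pose(frames[[i]], frames[[j]], pa, pb, step / 2, ideal$d_ss)
      else c(pa, pb, devm[cand[ci, 1L], cand[ci, 2L]])
    }
    poses <- poses[poses[, 3L] <= config$ss_bond_tolerance, , drop = FALSE]
    if (nrow(poses) == 0L) next
    poses <- poses[!duplicated(round(poses[, 1:2, drop = FALSE] / 0.02)), ,
                   drop = FALSE]

    best <- NULL
    for (ci in seq_len(nrow(poses))) {
      chi_a <- wrap_angle(poses[ci, 1L]); chi_b <- wrap_angle(poses[ci, 2L])
      sga <- sg_at(frames[[i]], chi_a)
      sgb <- sg_at(frames[[j]], chi_b)
      chi3 <- dihedral(res[[i]]$cb, sga, sgb, res[[j]]$cb)
      wdev <- min(vapply(config$chi3_windows,
                         function(w) abs(ang_diff(chi3, w[1L])) - w[2L],
                         numeric(1L)))
      if (wdev > 0) next
      th_a <- bond_angle(res[[i]]$cb, sga, sgb)
      th_b <- bond_angle(sga, sgb, res[[j]]$cb)
      if (abs(th_a - ideal$ang_cb_s_s) > config$angle_tolerance ||
          abs(th_b - ideal$ang_cb_s_s) > config$angle_tolerance) next
      en <- total_energy(chi_a, chi_b, chi3, th_a, th_b, energy,
                         breakdown = TRUE)
      wcen <- min(vapply(config$chi3_windows,
                         function(w) abs(ang_diff(chi3, w[1L])), numeric(1L)))
      cand_pose <- list(chi_a = chi_a, chi_b = chi_b, chi3 = chi3,
                        th_a = th_a, th_b = th_b,
                        ss = vnorm(sga - sgb), sga = sga, sgb = sgb,
                        en = en, wcen = wcen)
      if (is.null(best) ||
          en$energy < best$en$energy - 1e-12 ||
          (abs(en$energy - best$en$energy) <= 1e-12 &&
             (cand_pose$wcen < best$wcen - 1e-12 ||
                (abs(cand_pose$wcen - best$wcen) <= 1e-12 &&
                   chi_a < best$chi_a))))
        best <- cand_pose
    }
    if (is.null(best)) next
    if (!is.null(config$energy_cutoff) &&
        best$en$energy > config$energy_cutoff) next

    ra <- res[[i]]; rb <- res[[j]]
    preds[[length(preds) + 1L]] <- data.frame(
      chain1 = ra$chain, res1 = ra$resno, icode1 = ra$insert, aa1 = ra$aa,
      chain2 = rb$chain, res2 = rb$resno, icode2 = rb$insert, aa2 = rb$aa,
      chi1_a = best$chi_a, chi1_b = best$chi_b, chi3 = best$chi3,
      theta_a = best$th_a, theta_b = best$th_b, ss_distance = best$ss,
      e_chi1_a = best$en$e_chi1_a, e_chi1_b = best$en$e_chi1_b,
      e_chi3 = best$en$e_chi3, e_angle_a = best$en$e_angle_a,
      e_angle_b = best$en$e_angle_b, energy = best$en$energy,
      sum_bfactor = ra$mean_b + rb$mean_b,
      sg_a_x = best$sga[1L], sg_a_y = best$sga[2L], sg_a_z = best$sga[3L],
      sg_b_x = best$sgb[1L], sg_b_y = best$sgb[2L], sg_b_z = best$sgb[3L],
      is_native = paste(pmin(ra$key, rb$key), pmax(ra$key, rb$key)) %in%
        nat_keys,
      stringsAsFactors = FALSE)
  }
  if (!is.null(progress)) progress(1)

  if (length(preds) == 0L) {
    out <- data.frame(chain1 = character(), res1 = integer(),
                      icode1 = character(), aa1 = character(),
                      chain2 = character(), res2 = integer(),
                      icode2 = character(), aa2 = character(),
                      chi1_a = numeric(), chi1_b = numeric(),
                      chi3 = numeric(), theta_a = numeric(),
                      theta_b = numeric(), ss_distance = numeric(),
                      e_chi1_a = numeric(), e_chi1_b = numeric(),
                      e_chi3 = numeric(), e_angle_a = numeric(),
                      e_angle_b = numeric(), energy = numeric(),
                      sum_bfactor = numeric(),
                      sg_a_x = numeric(), sg_a_y = numeric(),
                      sg_a_z = numeric(), sg_b_x = numeric(),
                      sg_b_y = numeric(), sg_b_z = numeric(),
                      is_native = logical(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, preds)
    # canonical pair orientation, then deterministic output order
    flip <- out$chain1 > out$chain2 |
      (out$chain1 == out$chain2 &
         (out$res1 > out$res2 |
            (out$res1 == out$res2 & out$icode1 > out$icode2)))
    if (any(flip)) {
      sw <- function(x, a, b) { t <- x[[a]][flip]; x[[a]][flip] <- x[[b]][flip]
        x[[b]][flip] <- t; x }
      for (p in list(c("chain1", "chain2"), c("res1", "res2"),
                     c("icode1", "icode2"), c("aa1", "aa2"),
                     c("chi1_a", "chi1_b"), c("theta_a", "theta_b"),
                     c("e_chi1_a", "e_chi1_b"), c("e_angle_a", "e_angle_b"),
                     c("sg_a_x", "sg_b_x"), c("sg_a_y", "sg_b_y"),
                     c("sg_a_z", "sg_b_z")))
        out <- sw(out, p[1L], p[2L])
    }
    out <- out[order(out$chain1, out$res1, out$icode1,
                     out$chain2, out$res2, out$icode2), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("ss_predictions", "data.frame")
  attr(out, "n_pairs_considered") <- n_pairs
  out
}

#' @export
print.ss_predictions <- function(x, ...) {
  cat(sprintf("Disulfide scan: %d predicted bridge(s)\n", nrow(x)))
  if (nrow(x) > 0L)
    print.data.frame(x[, c("chain1", "res1", "aa1", "chain2", "res2", "aa2",
                           "chi3", "energy", "sum_bfactor", "is_native")],
                     digits = 4, ...)
  invisible(x)
}
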
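#' Extract native disulfide bridges from a structure
#'
#' A native bridge is any pair declared in an SSBOND record, plus any
#' cysteine pair whose file SG-SG distance is below `max_ss_dist`
#' (annotation in deposited files is not always complete). Duplicates are
#' merged. The native chi3 torsion and sulfur coordinates are measured
#' from the file coordinates.
#'
#' @param model An `ss_model`.
#' @param max_ss_dist SG-SG distance threshold for unannotated pairs,
#'   Angstrom.
#' @return A data frame with one row per native bridge: residue keys
#'   `key_a`, `key_b`, the native `chi3` (degrees, `NA` if CB or SG atoms
#'   are missing), and the native SG coordinates of both partners. May have
#'   zero rows.
#' @export
extract_native <- function(model, max_ss_dist = 2.5) {
  stopifnot(inherits(model, "ss_model"))
  atoms <- model$atom
  cys <- atoms[atoms$resid == "CYS", , drop = FALSE]
  sg <- cys[cys$elety == "SG", , drop = FALSE]

  pairs <- character(0)
  if (nrow(model$ssbonds) > 0L) {
    k1 <- res_key(model$ssbonds$chain1, model$ssbonds$resno1,
                  model$ssbonds$insert1)
    k2 <- res_key(model$ssbonds$chain2, model$ssbonds$resno2,
                  model$ssbonds$insert2)
    pairs <- paste(pmin(k1, k2), pmax(k1, k2), sep = "\r")
  }
  if (nrow(sg) >= 2L) {
    m <- as.matrix(sg[, c("x", "y", "z")])
    d <- sqrt(pmax(outer(rowSums(m^2), rowSums(m^2), "+") - 2 * tcrossprod(m), 0))
    hit <- which(upper.tri(d) & d < max_ss_dist, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      ka <- sg$reskey[hit[, 1L]]; kb <- sg$reskey[hit[, 2L]]
      pairs <- c(pairs, paste(pmin(ka, kb), pmax(ka, kb), sep = "\r"))
    }
  }
  pairs <- unique(pairs)
  if (length(pairs) == 0L)
    return(data.frame(key_a = character(), key_b = character(),
                      chi3 = numeric(),
                      sg_a_x = numeric(), sg_a_y = numeric(),
                      sg_a_z = numeric(), sg_b_x = numeric(),
                      sg_b_y = numeric(), sg_b_z = numeric(),
                      stringsAsFactors = FALSE))

  coord <- function(key, elety) {
    row <- atoms[atoms$reskey == key & atoms$elety == elety, , drop = FALSE]
    if (nrow(row) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    as.numeric(row[1L, c("x", "y", "z")])
  }
  out <- lapply(strsplit(pairs, "\r", fixed = TRUE), function(kk) {
    cba <- coord(kk[1L], "CB"); sga <- coord(kk[1L], "SG")
    cbb <- coord(kk[2L], "CB"); sgb <- coord(kk[2L], "SG")
    chi3 <- if (anyNA(c(cba, sga, sgb, cbb))) NA_real_
            else dihedral(cba, sga, sgb, cbb)
    data.frame(key_a = kk[1L], key_b = kk[2L], chi3 = chi3,
               sg_a_x = sga[1L], sg_a_y = sga[2L], sg_a_z = sga[3L],
               sg_b_x = sgb[1L], sg_b_y = sgb[2L], sg_b_z = sgb[3L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# chi1/chi3/theta angles of a native bridge measured from file coordinates
native_bridge_angles <- function(model, key_a, key_b) {
  atoms <- model$atom
  g <- function(key, e) {
    row <- atoms[atoms$reskey == key & atoms$elety == e, , drop = FALSE]
    if (nrow(row) == 0L) return(NULL)
    as.numeric(row[1L, c("x", "y", "z")])
  }
  na_ <- g(key_a, "N"); caa <- g(key_a, "CA"); cba <- g(key_a, "CB")
  sga <- g(key_a, "SG")
  nb <- g(key_b, "N"); cab <- g(key_b, "CA"); cbb <- g(key_b, "CB")
  sgb <- g(key_b, "SG")
  if (is.null(na_) || is.null(caa) || is.null(cba) || is.null(sga) ||
      is.null(nb) || is.null(cab) || is.null(cbb) || is.null(sgb))
    return(NULL)
  list(chi1_a = dihedral(na_, caa, cba, sga),
       chi1_b = dihedral(nb, cab, cbb, sgb),
       chi3 = dihedral(cba, sga, sgb, cbb),
       theta_a = bond_angle(cba, sga, sgb),
       theta_b = bond_angle(sga, sgb, cbb))
}

bin_counts <- function(x, width, lower = NULL, upper = NULL) {
  x <- x[is.finite(x)]
  if (length(x) == 0L)
    return(data.frame(lower = numeric(), count = integer()))
  if (is.null(lower)) lower <- floor(min(x) / width) * width
  if (is.null(upper)) upper <- ceiling(max(x) / width) * width
  if (upper <= lower) upper <- lower + width
  breaks <- seq(lower, upper, by = width)
  ct <- table(cut(x, breaks = breaks, include.lowest = TRUE, right = FALSE))
  # right-open bins except the last, so upper-boundary values are counted
  data.frame(lower = breaks[-length(breaks)], count = as.integer(ct),
             row.names = NULL)
}

#' Blind validation of the scan against native disulfides
#'
#' Runs the scan on each input structure using only backbone geometry (the
#' beta carbons are rebuilt and the file sulfur positions are never
#' consulted), then compares predictions with the native disulfides found
#' in the files. A native bridge counts as recovered when its residue pair
#' appears among the predictions; its chirality is correct when the sign of
#' the predicted chi3 matches the native sign. Over the chirality-correct
#' bridges, predicted chi3 is regressed on native chi3 by ordinary least
#' squares; over recovered bridges the distances between modeled and native
#' sulfur positions (both sulfurs pooled) summarize coordinate accuracy.
#' Native geometry is also scored with the energy model, yielding the
#' survey energy distribution.
#'
#' @param models A list of `ss_model` objects (or a single one).
#' @param config A [scan_config()].
#' @param energy An [energy_params()] object.
#' @param ideal An [ideal_params()] object.
#' @return An object of class `ss_survey_report`: counts and percentages of
#'   recovery and chirality agreement, the regression R-squared, the median
#'   sulfur displacement (Angstrom), chi3 (5-degree bins) and energy
#'   (0.25 kcal/mol bins) histograms with `energy_mean` and `energy_p90`,
#'   and a `bridges` data frame with the per-bridge detail.
#' @export
#' @examples
#' set <- build_survey_set(5, seed = 7)
#' rep <- blind_validate(lapply(set, `[[`, "model"))
#' rep$recovery_pct
blind_validate <- function(models, config = scan_config(),
                           energy = energy_params(),
                           ideal = ideal_params()) {
  if (inherits(models, "ss_model")) models <- list(models)
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, TRUE, "ss_model")))

  rows <- list()
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    nat <- extract_native(model)
    if (nrow(nat) == 0L) next
    preds <- scan_disulfides(model, config, energy, ideal)
    pk1 <- if (nrow(preds) > 0L)
      res_key(preds$chain1, preds$res1, preds$icode1) else character()
    pk2 <- if (nrow(preds) > 0L)
      res_key(preds$chain2, preds$res2, preds$icode2) else character()
    pk <- paste(pmin(pk1, pk2), pmax(pk1, pk2))
    for (bi in seq_len(nrow(nat))) {
      ka <- nat$key_a[bi]; kb <- nat$key_b[bi]
      hit <- match(paste(pmin(ka, kb), pmax(ka, kb)), pk)
      recovered <- !is.na(hit)
      pred_chi3 <- if (recovered) preds$chi3[hit] else NA_real_
      sgd <- c(NA_real_, NA_real_)
      if (recovered) {
        pa <- c(preds$sg_a_x[hit], preds$sg_a_y[hit], preds$sg_a_z[hit])
        pb <- c(preds$sg_b_x[hit], preds$sg_b_y[hit], preds$sg_b_z[hit])
        na_sg <- as.numeric(nat[bi, c("sg_a_x", "sg_a_y", "sg_a_z")])
        nb_sg <- as.numeric(nat[bi, c("sg_b_x", "sg_b_y", "sg_b_z")])
        # pair each modeled sulfur with the native sulfur of its residue
        if (pk1[hit] != ka) { tmp <- pa; pa <- pb; pb <- tmp }
        sgd <- c(vnorm(pa - na_sg), vnorm(pb - nb_sg))
      }
      ang <- native_bridge_angles(model, ka, kb)
      nat_energy <- if (is.null(ang)) NA_real_
      else total_energy(ang$chi1_a, ang$chi1_b, ang$chi3,
                        ang$theta_a, ang$theta_b, energy)
      rows[[length(rows) + 1L]] <- data.frame(
        structure = model$source_id, model_id = model$model_id,
        key_a = ka, key_b = kb,
        native_chi3 = nat$chi3[bi], predicted_chi3 = pred_chi3,
        recovered = recovered,
        chirality_correct = recovered & !is.na(nat$chi3[bi]) &
          sign(pred_chi3) == sign(nat$chi3[bi]),
        sg_dist_a = sgd[1L], sg_dist_b = sgd[2L],
        native_energy = nat_energy,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    stop("no native disulfide bridges found in the input structures",
         call. = FALSE)
  bridges <- do.call(rbind, rows)
  rownames(bridges) <- NULL

  n_native <- nrow(bridges)
  n_recovered <- sum(bridges$recovered)
  chir <- bridges$chirality_correct %in% TRUE
  n_chir <- sum(chir)
  r2 <- NA_real_
  if (n_chir >= 2L && stats::sd(bridges$native_chi3[chir]) > 0) {
    fit <- stats::lm(predicted_chi3 ~ native_chi3, data = bridges[chir, ])
    r2 <- suppressWarnings(summary(fit)$r.squared)
  }
  sg_pool <- c(bridges$sg_dist_a[bridges$recovered],
               bridges$sg_dist_b[bridges$recovered])
  en <- bridges$native_energy[is.finite(bridges$native_energy)]

  structure(list(
    n_structures = length(unique(paste(bridges$structure, bridges$model_id))),
    n_native = n_native,
    n_recovered = n_recovered,
    recovery_pct = 100 * n_recovered / n_native,
    n_chirality_correct = n_chir,
    chirality_pct = if (n_recovered > 0L) 100 * n_chir / n_recovered
                    else NA_real_,
    r_squared = r2,
    median_sg_dist = if (length(sg_pool) > 0L)
      stats::median(sg_pool, na.rm = TRUE) else NA_real_,
    chi3_histogram = bin_counts(bridges$native_chi3, 5, -180, 180),
    energy_histogram = bin_counts(en, 0.25, 0),
    energy_mean = if (length(en) > 0L) mean(en) else NA_real_,
    energy_p90 = if (length(en) > 0L)
      unname(stats::quantile(en, 0.9)) else NA_real_,
    bridges = bridges), class = "ss_survey_report")
}

#' Filter a candidate list down to a survey set
#'
#' Keeps structures that contain at least one native disulfide bridge and
#' whose recorded resolution is at most `max_resolution` Angstrom.
#' Structures without a recorded resolution are excluded (with a message).
#' Redundancy filtering by sequence identity is up to the caller: supply a
#' pre-clustered, non-redundant structure list.
#'
#' @param models A list of `ss_model` objects.
#' @param max_resolution Resolution cutoff, Angstrom.
#' @return The filtered list.
#' @export
select_survey_set <- function(models, max_resolution = 2.0) {
  stopifnot(all(vapply(models, inherits, TRUE, "ss_model")))
  keep <- vapply(models, function(m) {
    if (is.na(m$resolution)) {
      message("excluded '", m$source_id, "': no recorded resolution")
      return(FALSE)
    }
    if (m$resolution > max_resolution) return(FALSE)
    nrow(extract_native(m)) >= 1L
  }, logical(1L))
  models[keep]
}

#' Write a survey report to JSON (and optionally histogram CSVs and plots)
#'
#' @param report An [blind_validate()] result.
#' @param json_file Path for the JSON summary.
#' @param hist_prefix Optional path prefix; writes
#'   `<prefix>_chi3_histogram.csv` and `<prefix>_energy_histogram.csv`.
#' @param plot_prefix Optional path prefix; writes PNG plots of the two
#'   histograms and the predicted-vs-native chi3 scatter.
#' @return Invisibly, the paths written.
#' @export
write_survey_report <- function(report, json_file, hist_prefix = NULL,
                                plot_prefix = NULL) {
  stopifnot(inherits(report, "ss_survey_report"))
  scalar <- report[c("n_structures", "n_native", "n_recovered",
                     "recovery_pct", "n_chirality_correct", "chirality_pct",
                     "r_squared", "median_sg_dist", "energy_mean",
                     "energy_p90")]
  jsonlite::write_json(scalar, json_file, auto_unbox = TRUE, digits = NA,
                       na = "null")
  written <- json_file
  if (!is.null(hist_prefix)) {
    f1 <- paste0(hist_prefix, "_chi3_histogram.csv")
    f2 <- paste0(hist_prefix, "_energy_histogram.csv")
    utils::write.csv(report$chi3_histogram, f1, row.names = FALSE)
    utils::write.csv(report$energy_histogram, f2, row.names = FALSE)
    written <- c(written, f1, f2)
  }
  if (!is.null(plot_prefix)) {
    br <- report$bridges
    p1 <- paste0(plot_prefix, "_chi3_histogram.png")
    grDevices::png(p1, width = 600, height = 400)
    graphics::barplot(report$chi3_histogram$count,
                      names.arg = report$chi3_histogram$lower,
                      xlab = "native chi3 (deg, bin lower edge)",
                      ylab = "count", main = "Native chi3 distribution")
    grDevices::dev.off()
    p2 <- paste0(plot_prefix, "_energy_histogram.png")
    grDevices::png(p2, width = 600, height = 400)
    graphics::barplot(report$energy_histogram$count,
                      names.arg = report$energy_histogram$lower,
                      xlab = "energy (kcal/mol, bin lower edge)",
                      ylab = "count", main = "Native bridge energies")
    grDevices::dev.off()
    p3 <- paste0(plot_prefix, "_chi3_scatter.png")
    grDevices::png(p3, width = 500, height = 500)
    ok <- br$chirality_correct %in% TRUE
    graphics::plot(br$native_chi3[ok], br$predicted_chi3[ok],
                   xlab = "native chi3 (deg)", ylab = "predicted chi3 (deg)",
                   main = sprintf("R^2 = %.3f", report$r_squared))
    graphics::abline(0, 1, lty = 2)
    grDevices::dev.off()
    written <- c(written, p1, p2, p3)
  }
  invisible(written)
}

#' @export
print.ss_survey_report <- function(x, ...) {
  cat("Blind-validation survey report\n")
  cat(sprintf("  structures: %d, native bridges: %d\n",
              x$n_structures, x$n_native))
  cat(sprintf("  recovered: %d (%.1f%%), chirality correct: %d (%.1f%% of recovered)\n",
              x$n_recovered, x$recovery_pct, x$n_chirality_correct,
              x$chirality_pct))
  cat(sprintf("  chi3 regression R^2: %s, median SG displacement: %s A\n",
              format(x$r_squared, digits = 4),
              format(x$median_sg_dist, digits = 3)))
  cat(sprintf("  native-geometry energy: mean %.2f, 90th percentile %.2f kcal/mol\n",
              x$energy_mean, x$energy_p90))
  invisible(x)
}
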
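#' Whole-chain B-factor profile
#'
#' Per-residue mean B-factors over the backbone (N, CA, C, O) and
#' beta-carbon atoms -- the same per-residue value used in the Sigma-B pair
#' metric -- together with the minimum, maximum and mean across residues.
#' The range and mean give users the structure-specific scale against which
#' a candidate bridge's mobility should be judged, since raw B-factors are
#' not comparable between structures (they depend on refinement, resolution
#' and crystal contacts).
#'
#' @param model An `ss_model`.
#' @return An object of class `ss_bfactor_profile`: a list with
#'   `per_residue` (data frame: `reskey`, `chain`, `resno`, `insert`,
#'   `mean_b`), and scalars `b_min`, `b_max`, `b_mean` (Angstrom squared).
#' @export
#' @examples
#' fx <- build_ideal_bridge(bridge_spec(bfactor_plan = "gradient"))
#' bfactor_profile(fx$model)
bfactor_profile <- function(model) {
  stopifnot(inherits(model, "ss_model"))
  atoms <- model$atom
  keys <- unique(atoms$reskey)
  idx <- split(seq_len(nrow(atoms)), factor(atoms$reskey, levels = keys))
  mb <- vapply(idx, function(ii)
    residue_mean_bfactor(atoms[ii, , drop = FALSE]), numeric(1L))
  ok <- !is.na(mb)
  if (!any(ok))
    stop("no residue with any of N, CA, C, O, CB atoms; B-factor profile undefined",
         call. = FALSE)
  first <- vapply(idx, `[`, 1L, 1L)
  per <- data.frame(reskey = keys[ok],
                    chain = atoms$chain[first][ok],
                    resno = atoms$resno[first][ok],
                    insert = atoms$insert[first][ok],
                    mean_b = unname(mb[ok]),
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(per_residue = per,
                 b_min = min(per$mean_b),
                 b_max = max(per$mean_b),
                 b_mean = mean(per$mean_b)),
            class = "ss_bfactor_profile")
}

#' Map residues onto the 512-step blue/red B-factor color scale
#'
#' Residue mean B-factors are normalized to 512 discrete values between the
#' structure's minimum and maximum: index
#' `round((b - b_min) / (b_max - b_min) * 511)` (half-up rounding). Indices
#' 0-255 fall on a 256-step blue scale (low mobility), indices 256-511 on a
#' 256-step red scale (high mobility). When every residue has the same
#' B-factor all indices are 0 (blue) by convention. The mapping is monotone
#' in B and invariant under affine rescaling of all B-factors.
#'
#' @param profile An [bfactor_profile()] result.
#' @param reskey Residue key(s) to colorize; default all residues in the
#'   profile.
#' @return A data frame with `reskey`, `mean_b`, `index` (0-511), `channel`
#'   (`"blue"` or `"red"`).
#' @export
colorize_bfactor <- function(profile, reskey = NULL) {
  stopifnot(inherits(profile, "ss_bfactor_profile"))
  per <- profile$per_residue
  if (is.null(reskey)) reskey <- per$reskey
  pos <- match(reskey, per$reskey)
  if (anyNA(pos))
    stop("residue(s) not in profile: ",
         paste(reskey[is.na(pos)], collapse = ", "), call. = FALSE)
  b <- per$mean_b[pos]
  span <- profile$b_max - profile$b_min
  index <- if (span <= 0) rep(0L, length(b))
           else as.integer(floor((b - profile$b_min) / span * 511 + 0.5))
  data.frame(reskey = reskey, mean_b = b, index = index,
             channel = ifelse(index >= 256L, "red", "blue"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.ss_bfactor_profile <- function(x, ...) {
  cat(sprintf("B-factor profile over %d residues: min %.2f, max %.2f, mean %.2f\n",
              nrow(x$per_residue), x$b_min, x$b_max, x$b_mean))
  invisible(x)
}
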
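## PDB input/output.
##
## Hand-rolled fixed-column parsing because the scan needs per-model atom
## tables, SSBOND records, occupancy-based altloc resolution and precise
## error reporting, and the mutant exporter needs full control of the
## emitted records.

res_key <- function(chain, resno, insert = "") {
  insert <- ifelse(is.na(insert) | insert == " ", "", insert)
  sprintf("%s|%d|%s", chain, as.integer(resno), insert)
}

split_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  data.frame(chain = vapply(parts, `[`, "", 1L),
             resno = as.integer(vapply(parts, `[`, "", 2L)),
             insert = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", ""),
             stringsAsFactors = FALSE)
}

# tolerant fixed-column substring: short lines yield ""
fcol <- function(lines, from, to) {
  out <- substr(lines, from, to)
  out[is.na(out)] <- ""
  out
}

num_field <- function(txt, line_no, what, required = TRUE) {
  s <- trimws(txt)
  out <- suppressWarnings(as.numeric(s))
  bad <- is.na(out) & (required | s != "")
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("PDB parse error at line %d: malformed %s field '%s'",
                 line_no[i], what, s[i]), call. = FALSE)
  }
  out
}

guess_element <- function(name) {
  el <- gsub("[^A-Za-z]", "", name)
  toupper(substr(el, 1L, 1L))
}

parse_atom_block <- function(lines, line_no) {
  rec <- fcol(lines, 1L, 6L)
  is_atom <- startsWith(rec, "ATOM")
  is_het <- startsWith(rec, "HETATM")
  resname <- trimws(fcol(lines, 18L, 20L))
  keep <- is_atom | (is_het & resname == "MSE")
  if (!any(keep)) return(NULL)
  ln <- line_no[keep]
  lines <- lines[keep]
  resname <- resname[keep]

  elety <- trimws(fcol(lines, 13L, 16L))
  alt <- fcol(lines, 17L, 17L)
  alt[alt == " "] <- ""
  chain <- fcol(lines, 22L, 22L)
  resno <- num_field(fcol(lines, 23L, 26L), ln, "residue number")
  insert <- trimws(fcol(lines, 27L, 27L))
  x <- num_field(fcol(lines, 31L, 38L), ln, "x coordinate")
  y <- num_field(fcol(lines, 39L, 46L), ln, "y coordinate")
  z <- num_field(fcol(lines, 47L, 54L), ln, "z coordinate")
  o <- num_field(fcol(lines, 55L, 60L), ln, "occupancy", required = FALSE)
  b <- num_field(fcol(lines, 61L, 66L), ln, "B-factor", required = FALSE)
  o[is.na(o)] <- 1.0
  b[is.na(b)] <- 0.0
  elesy <- toupper(trimws(fcol(lines, 77L, 78L)))
  miss <- elesy == ""
  elesy[miss] <- guess_element(elety[miss])

  atoms <- data.frame(elety = elety, alt = alt, resid = resname,
                      chain = chain, resno = as.integer(resno),
                      insert = insert, x = x, y = y, z = z, o = o, b = b,
                      elesy = elesy, stringsAsFactors = FALSE)

  # selenomethionine parses as methionine; hydrogens are dropped
  mse <- atoms$resid == "MSE"
  if (any(mse)) {
    atoms$resid[mse] <- "MET"
    se <- mse & atoms$elety == "SE"
    atoms$elety[se] <- "SD"
    atoms$elesy[se] <- "S"
  }
  atoms <- atoms[!(atoms$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0L) return(NULL)

  if (any(atoms$b < 0))
    warning("negative B-factor values present; accepted as given", call. = FALSE)
  if (any(atoms$o < 0 | atoms$o > 1))
    warning("occupancancy values outside [0, 1] present", call. = FALSE)

  # altloc resolution: highest occupancy wins, ties to the alphabetically
  # first altloc, so the retained model is single-conformer and deterministic
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  ord <- order(match(key, unique(key)), -atoms$o, atoms$alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$insert,
                                   atoms$elety, sep = "\r")), , drop = FALSE]
  atoms$alt <- NULL
  rownames(atoms) <- NULL
  atoms$reskey <- res_key(atoms$chain, atoms$resno, atoms$insert)
  atoms
}

parse_ssbond <- function(lines) {
  if (length(lines) == 0L)
    return(data.frame(chain1 = character(), resno1 = integer(),
                      insert1 = character(), chain2 = character(),
                      resno2 = integer(), insert2 = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    chain1 = fcol(lines, 16L, 16L),
    resno1 = as.integer(trimws(fcol(lines, 18L, 21L))),
    insert1 = trimws(fcol(lines, 22L, 22L)),
    chain2 = fcol(lines, 30L, 30L),
    resno2 = as.integer(trimws(fcol(lines, 32L, 35L))),
    insert2 = trimws(fcol(lines, 36L, 36L)),
    stringsAsFactors = FALSE)
}

new_ss_model <- function(model_id, atoms, ssbonds, source_id, resolution = NA_real_) {
  structure(list(model_id = model_id, atom = atoms, ssbonds = ssbonds,
                 source_id = source_id, resolution = resolution),
            class = "ss_model")
}

#' Read a PDB-format structure
#'
#' Parses ATOM, HETATM (selenomethionine only), MODEL/ENDMDL, SSBOND and
#' REMARK 2 resolution records. Alternate locations are resolved to the
#' highest-occupancy conformer (ties broken alphabetically), hydrogens are
#' dropped, and residue identity is the triple (chain, residue number,
#' insertion code) -- PDB numbering is preserved verbatim, including gaps
#' and insertion codes.
#'
#' @param file Path to a PDB file, or PDB-format text (a single string with
#'   newlines, or a character vector of lines).
#' @param source_id Provenance label stored on each model; defaults to the
#'   file name (or `"<text>"` for literal input).
#' @return A list of `ss_model` objects, one per MODEL block (exactly one
#'   for files without MODEL records, with `model_id` 1). Each holds an
#'   `atom` data frame (`elety`, `resid`, `chain`, `resno`, `insert`,
#'   `x`, `y`, `z`, `o`, `b`, `elesy`, `reskey`), an `ssbonds` data frame of
#'   native disulfide pairs, the `source_id`, and the `resolution` in
#'   Angstrom (`NA` if not recorded).
#' @export
#' @examples
#' fx <- build_ideal_bridge(bridge_spec())
#' txt <- write_pdb(fx$model)
#' mods <- read_pdb(txt)
#' length(mods)
read_pdb <- function(file, source_id = NULL) {
  if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    lines <- readLines(file, warn = FALSE)
    if (is.null(source_id)) source_id <- basename(file)
  } else {
    lines <- unlist(strsplit(as.character(file), "\n", fixed = TRUE))
    if (is.null(source_id)) source_id <- "<text>"
  }
  if (length(lines) == 0L)
    stop("no coordinates: empty PDB input", call. = FALSE)

  rec <- fcol(lines, 1L, 6L)
  ssb <- parse_ssbond(lines[startsWith(rec, "SSBOND")])

  resolution <- NA_real_
  rem2 <- lines[startsWith(rec, "REMARK") &
                  trimws(fcol(lines, 8L, 10L)) == "2" &
                  grepl("RESOLUTION", lines)]
  if (length(rem2) > 0L) {
    m <- regmatches(rem2[1L], regexpr("[0-9]+\\.?[0-9]*", rem2[1L]))
    if (length(m) == 1L) resolution <- as.numeric(m)
  }

  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) == 0L) {
    blocks <- list(seq_along(lines))
    ids <- 1L
  } else {
    ends <- which(trimws(rec) == "ENDMDL")
    blocks <- list()
    ids <- integer()
    for (k in seq_along(model_starts)) {
      s <- model_starts[k]
      e <- ends[ends > s]
      e <- if (length(e)) e[1L] else length(lines)
      blocks[[k]] <- seq(s, e)
      id <- suppressWarnings(as.integer(trimws(substr(lines[s], 7L, 14L))))
      ids[k] <- if (is.na(id)) k else id
    }
    if (anyDuplicated(ids)) ids <- seq_along(blocks)
  }

  models <- list()
  for (k in seq_along(blocks)) {
    idx <- blocks[[k]]
    atoms <- parse_atom_block(lines[idx], idx)
    if (is.null(atoms)) next
    mss <- validate_ssbonds(ssb, atoms)
    models[[length(models) + 1L]] <-
      new_ss_model(ids[k], atoms, mss, source_id, resolution)
  }
  if (length(models) == 0L)
    stop("no coordinates: PDB input contains no ATOM records", call. = FALSE)
  models
}

validate_ssbonds <- function(ssb, atoms) {
  if (nrow(ssb) == 0L) return(ssb)
  k1 <- res_key(ssb$chain1, ssb$resno1, ssb$insert1)
  k2 <- res_key(ssb$chain2, ssb$resno2, ssb$insert2)
  cys <- unique(atoms$reskey[atoms$resid == "CYS"])
  ok <- k1 %in% cys & k2 %in% cys
  if (any(!ok))
    warning(sprintf("%d SSBOND record(s) do not reference CYS residues present in the model; dropped",
                    sum(!ok)), call. = FALSE)
  out <- ssb[ok, , drop = FALSE]
  out[!duplicated(paste(pmin(k1, k2)[ok], pmax(k1, k2)[ok])), , drop = FALSE]
}

#' Retrieve a PDB entry by identifier
#'
#' Downloads the PDB-format file for a 4-character PDB identifier and
#' caches it on disk, so repeated calls (and offline sessions with a warm
#' cache) never touch the network. The rest of the package is fully usable
#' without this function.
#'
#' @param pdb_id A 4-character PDB identifier (digit followed by three
#'   alphanumerics), case-insensitive.
#' @param cache_dir Directory for cached downloads. Defaults to
#'   `getOption("ssbridge.cache")`, falling back to the user cache
#'   directory.
#' @param base_url Download URL template directory.
#' @return The entry's PDB-format text as a character vector of lines.
#' @export
fetch_pdb <- function(pdb_id,
                      cache_dir = getOption("ssbridge.cache",
                                            tools::R_user_dir("ssbridge", "cache")),
                      base_url = "https://files.rcsb.org/download") {
  if (!is.character(pdb_id) || length(pdb_id) != 1L ||
      !grepl("^[0-9][A-Za-z0-9]{3}$", pdb_id))
    stop("invalid PDB identifier '", paste(pdb_id, collapse = ","),
         "': expected a digit followed by three alphanumeric characters",
         call. = FALSE)
  pdb_id <- tolower(pdb_id)
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  dest <- file.path(cache_dir, paste0(pdb_id, ".pdb"))
  if (!file.exists(dest)) {
    url <- sprintf("%s/%s.pdb", base_url, toupper(pdb_id))
    old <- options(timeout = 30); on.exit(options(old))
    ok <- tryCatch(
      utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0L,
      error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok || !file.exists(dest) || file.size(dest) == 0L) {
      unlink(dest)
      stop("retrieval failed for PDB entry '", pdb_id,
           "' (network unavailable or unknown identifier)", call. = FALSE)
    }
  }
  readLines(dest, warn = FALSE)
}

format_atom_line <- function(serial, elety, resid, chain, resno, insert,
                             x, y, z, o, b, elesy) {
  name4 <- ifelse(nchar(elety) >= 4L, substr(elety, 1L, 4L),
                  sprintf(" %-3s", elety))
  sprintf("ATOM  %5d %s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, resid, chain, resno,
          ifelse(insert == "", " ", insert), x, y, z, o, b, elesy)
}

format_ssbond_lines <- function(ssb) {
  if (nrow(ssb) == 0L) return(character())
  sprintf("SSBOND %3d CYS %1s %4d%1s   CYS %1s %4d%1s",
          seq_len(nrow(ssb)), ssb$chain1, ssb$resno1,
          ifelse(ssb$insert1 == "", " ", ssb$insert1),
          ssb$chain2, ssb$resno2,
          ifelse(ssb$insert2 == "", " ", ssb$insert2))
}

#' Write structures in PDB format
#'
#' Emits SSBOND, ATOM and (for more than one model) MODEL/ENDMDL records.
#' Reading the output back with [read_pdb()] reproduces the retained record
#' set losslessly: coordinates to 0.001 Angstrom, occupancies and B-factors
#' to 0.01.
#'
#' @param models An `ss_model` or a list of them.
#' @param file Optional path; when `NULL` the text is returned.
#' @return Invisibly (or visibly when `file = NULL`) the PDB text as a
#'   character vector of lines.
#' @export
write_pdb <- function(models, file = NULL) {
  if (inherits(models, "ss_model")) models <- list(models)
  stopifnot(length(models) >= 1L, all(vapply(models, inherits, TRUE, "ss_model")))
  out <- character()
  res <- models[[1L]]$resolution
  if (!is.na(res))
    out <- c(out, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.", res))
  out <- c(out, format_ssbond_lines(models[[1L]]$ssbonds))
  multi <- length(models) > 1L
  for (m in models) {
    a <- m$atom
    if (multi) out <- c(out, sprintf("MODEL %8d", m$model_id))
    out <- c(out, format_atom_line(seq_len(nrow(a)), a$elety, a$resid, a$chain,
                                   a$resno, a$insert, a$x, a$y, a$z, a$o, a$b,
                                   a$elesy))
    if (multi) out <- c(out, "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Export a mutant structure with engineered cysteines
#'
#' For every residue in the selected predictions: the residue type becomes
#' CYS, side-chain atoms beyond the beta carbon are removed, a CB atom is
#' kept (or constructed from the backbone for glycine), and an SG atom is
#' written at the prediction's modeled coordinates with occupancy 1.00 and
#' the B-factor copied from the residue's CA. An SSBOND record is emitted
#' for each predicted pair; all untouched residues and pre-existing
#' disulfide annotations are written verbatim. The output is intended for
#' molecular dynamics setup or import into modeling packages.
#'
#' @param model An `ss_model`.
#' @param predictions Rows of a scan result ([scan_disulfides()]) selecting
#'   the bridges to build. May be empty, in which case the unmodified model
#'   is written.
#' @param file Optional output path.
#' @param ideal [ideal_params()] used when a glycine CB must be built.
#' @return The PDB text (character lines), invisibly when `file` is given.
#' @export
write_mutant_pdb <- function(model, predictions, file = NULL,
                             ideal = ideal_params()) {
  stopifnot(inherits(model, "ss_model"))
  predictions <- as.data.frame(predictions)
  if (nrow(predictions) == 0L) return(write_pdb(model, file))

  keys_a <- res_key(predictions$chain1, predictions$res1, predictions$icode1)
  keys_b <- res_key(predictions$chain2, predictions$res2, predictions$icode2)
  all_keys <- c(keys_a, keys_b)
  if (anyDuplicated(all_keys))
    stop("mutant export: a residue participates in more than one selected pair",
         call. = FALSE)
  missing <- setdiff(all_keys, unique(model$atom$reskey))
  if (length(missing) > 0L)
    stop("mutant export: prediction references residue(s) absent from the model: ",
         paste(missing, collapse = ", "), call. = FALSE)

  atoms <- model$atom
  sg_mat <- rbind(as.matrix(predictions[, c("sg_a_x", "sg_a_y", "sg_a_z")]),
                  as.matrix(predictions[, c("sg_b_x", "sg_b_y", "sg_b_z")]))
  keep_rows <- rep(TRUE, nrow(atoms))
  new_atoms <- list()

  for (i in seq_along(all_keys)) {
    key <- all_keys[i]
    sel <- which(atoms$reskey == key)
    ra <- atoms[sel, , drop = FALSE]
    if (any(ra$resid == "CYS"))
      warning("native cysteine ", key,
              " re-posed: SG moved to the modeled position", call. = FALSE)
    bb <- c("N", "CA", "C", "O", "OXT", "CB")
    drop <- sel[!(ra$elety %in% bb) ]
    keep_rows[drop] <- FALSE
    atoms$resid[sel] <- "CYS"
    ca_row <- ra[ra$elety == "CA", , drop = FALSE]
    if (nrow(ca_row) == 0L)
      stop("mutant export: residue ", key, " lacks a CA atom", call. = FALSE)
    tmpl <- ca_row[1L, , drop = FALSE]
    if (!any(ra$elety == "CB")) {
      nr <- ra[ra$elety == "N", , drop = FALSE]
      cr <- ra[ra$elety == "C", , drop = FALSE]
      if (nrow(nr) == 0L || nrow(cr) == 0L)
        stop("mutant export: cannot build CB for ", key,
             " (incomplete backbone)", call. = FALSE)
      cb <- construct_cbeta(as.numeric(nr[1L, c("x", "y", "z")]),
                            as.numeric(tmpl[, c("x", "y", "z")]),
                            as.numeric(cr[1L, c("x", "y", "z")]), ideal)
      cbrow <- tmpl
      cbrow$elety <- "CB"; cbrow$elesy <- "C"; cbrow$resid <- "CYS"
      cbrow[, c("x", "y", "z")] <- as.list(cb)
      new_atoms[[length(new_atoms) + 1L]] <- cbrow
    }
    sgrow <- tmpl
    sgrow$elety <- "SG"; sgrow$elesy <- "S"
    sgrow[, c("x", "y", "z")] <- as.list(sg_mat[i, ])
    sgrow$o <- 1.00
    sgrow$b <- ca_row$b[1L]
    sgrow$resid <- "CYS"
    new_atoms[[length(new_atoms) + 1L]] <- sgrow
  }

  atoms <- atoms[keep_rows, , drop = FALSE]
  # remove any pre-existing SG of re-posed cysteines, then insert new atoms
  atoms <- atoms[!(atoms$reskey %in% all_keys & atoms$elety == "SG"), , drop = FALSE]
  if (length(new_atoms) > 0L) {
    add <- do.call(rbind, new_atoms)
    atoms <- rbind(atoms, add)
    # restore residue-contiguous file order
    atoms <- atoms[order(match(atoms$reskey, unique(model$atom$reskey))), , drop = FALSE]
  }
  rownames(atoms) <- NULL

  ka <- split_key(keys_a); kb <- split_key(keys_b)
  new_ssb <- data.frame(chain1 = ka$chain, resno1 = ka$resno, insert1 = ka$insert,
                        chain2 = kb$chain, resno2 = kb$resno, insert2 = kb$insert,
                        stringsAsFactors = FALSE)
  old <- model$ssbonds
  if (nrow(old) > 0L) {
    ok1 <- res_key(old$chain1, old$resno1, old$insert1)
    ok2 <- res_key(old$chain2, old$resno2, old$insert2)
    old <- old[!(ok1 %in% all_keys | ok2 %in% all_keys), , drop = FALSE]
  }
  ssb <- rbind(old, new_ssb)

  mut <- new_ss_model(model$model_id, atoms, ssb, model$source_id,
                      model$resolution)
  write_pdb(mut, file)
}

#' Write scan predictions as CSV
#'
#' Columns: `chain1,res1,aa1,chain2,res2,aa2,chi3_deg,energy_kcal_mol,
#' sum_bfactor`, one row per prediction. Angles, energies and B-factor sums
#' are printed with 2 decimal places. The output can be sorted on any of
#' the emitted columns; ties preserve the original scan order.
#'
#' @param predictions A scan result ([scan_disulfides()]).
#' @param file Optional output path.
#' @param sort_by Column to sort on (one of the emitted column names).
#' @param descending Sort in decreasing order?
#' @return The CSV text (character lines); invisibly when `file` is given.
#' @export
predictions_csv <- function(predictions, file = NULL, sort_by = "energy_kcal_mol",
                            descending = FALSE) {
  p <- as.data.frame(predictions)
  cols <- c("chain1", "res1", "aa1", "chain2", "res2", "aa2",
            "chi3_deg", "energy_kcal_mol", "sum_bfactor")
  if (!sort_by %in% cols)
    stop("unknown sort column '", sort_by, "'; expected one of: ",
         paste(cols, collapse = ", "), call. = FALSE)
  if (nrow(p) > 0L) {
    tab <- data.frame(chain1 = p$chain1,
                      res1 = paste0(p$res1, p$icode1),
                      aa1 = p$aa1,
                      chain2 = p$chain2,
                      res2 = paste0(p$res2, p$icode2),
                      aa2 = p$aa2,
                      chi3_deg = p$chi3,
                      energy_kcal_mol = p$energy,
                      sum_bfactor = p$sum_bfactor,
                      stringsAsFactors = FALSE)
    ord <- order(tab[[sort_by]], decreasing = descending, method = "radix")
    tab <- tab[ord, , drop = FALSE]
    for (cc in c("chi3_deg", "energy_kcal_mol", "sum_bfactor"))
      tab[[cc]] <- sprintf("%.2f", tab[[cc]])
    body <- do.call(paste, c(tab, sep = ","))
  } else {
    body <- character()
  }
  out <- c(paste(cols, collapse = ","), body)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' @export
print.ss_model <- function(x, ...) {
  nres <- length(unique(x$atom$reskey))
  cat(sprintf("ss_model '%s' (model %d): %d residues, %d atoms, %d SSBOND record(s)%s\n",
              x$source_id, x$model_id, nres, nrow(x$atom), nrow(x$ssbonds),
              if (is.na(x$resolution)) ""
              else sprintf(", resolution %.2f A", x$resolution)))
  invisible(x)
}
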
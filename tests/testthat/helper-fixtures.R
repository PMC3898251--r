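# Shared helpers: rigid-body transforms, tiny hand-built models, CLI runner.

rnorm3_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# random proper rotation + translation, seeded by the caller
random_rigid_transform <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  rot <- qr.Q(qr_)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  list(rot = rot, shift = rnorm(3, sd = 20))
}

apply_transform_pt <- function(tr, p) as.numeric(tr$rot %*% p + tr$shift)

apply_transform_model <- function(tr, model) {
  xyz <- as.matrix(model$atom[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(tr$rot), 2, tr$shift, "+")
  model$atom[, c("x", "y", "z")] <- xyz
  model
}

# minimal model: translated copies of the ideal residue template, one per
# row of `centers`; b may be a vector (per residue) or list (per atom)
toy_model <- function(centers, resnames = NULL, b = 10, chain = "A",
                      drop_atoms = NULL) {
  n <- nrow(centers)
  if (is.null(resnames)) resnames <- rep("ALA", n)
  tmpl <- ideal_residue()
  blocks <- lapply(seq_len(n), function(i) {
    coords <- lapply(tmpl, function(p) p + as.numeric(centers[i, ]))
    if (!is.null(drop_atoms))
      coords <- coords[setdiff(names(coords), drop_atoms[[i]])]
    bi <- if (is.list(b)) b[[i]] else rep(b[min(i, length(b))],
                                          length(coords))
    ssbridge:::atom_rows(coords, resnames[i], chain, i, bi)
  })
  atoms <- do.call(rbind, blocks)
  rownames(atoms) <- NULL
  ssbridge:::new_ss_model(
    1L, atoms,
    data.frame(chain1 = character(), resno1 = integer(), insert1 = character(),
               chain2 = character(), resno2 = integer(), insert2 = character(),
               stringsAsFactors = FALSE),
    "toy")
}

run_cli <- function(args, input = NULL) {
  rscript <- file.path(R.home("bin"), "Rscript")
  script <- system.file("cli", "ssbridge.R", package = "ssbridge")
  out <- suppressWarnings(
    system2(rscript, c(shQuote(script), args), stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(status = if (is.null(status)) 0L else status, output = out)
}

expect_pair_in <- function(preds, res_a, res_b) {
  expect_true(any(preds$res1 == res_a & preds$res2 == res_b |
                    preds$res1 == res_b & preds$res2 == res_a))
}
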
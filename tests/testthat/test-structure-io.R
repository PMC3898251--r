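# PDB parsing, writing, mutant export and CSV output.

pdb_lines <- function(...) c(...)

ALTLOC_FIXTURE <- pdb_lines(
  "ATOM      1  N   ALA A   1       1.458   0.000   0.000  1.00 10.00           N",
  "ATOM      2  CA AALA A   1       0.000   0.000   0.000  0.70 10.00           C",
  "ATOM      3  CA BALA A   1       0.500   0.500   0.500  0.30 12.00           C",
  "ATOM      4  C   ALA A   1      -0.546   1.424   0.000  1.00 10.00           C",
  "END")

test_that("multi-model files yield one model per MODEL block", {
  txt <- build_multimodel(2, bridge_spec())
  mods <- read_pdb(txt)
  expect_length(mods, 2)
  expect_equal(vapply(mods, `[[`, 1L, "model_id"), 1:2)
  # sigma = 0: identical coordinates across models
  expect_equal(mods[[1]]$atom[, c("x", "y", "z")],
               mods[[2]]$atom[, c("x", "y", "z")])
  expect_length(read_pdb(build_multimodel(3, bridge_spec())), 3)
  # single-block files yield exactly one model with id 1
  one <- read_pdb(write_pdb(build_ideal_bridge(bridge_spec())$model))
  expect_length(one, 1)
  expect_equal(one[[1]]$model_id, 1L)
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  m <- read_pdb(ALTLOC_FIXTURE)[[1]]
  ca <- m$atom[m$atom$elety == "CA", ]
  expect_equal(nrow(ca), 1)
  expect_equal(as.numeric(ca[, c("x", "y", "z")]), c(0, 0, 0))
  expect_equal(ca$b, 10)
  # occupancy tie: the alphabetically first altloc wins
  tie <- sub("  0.70", "  0.30", ALTLOC_FIXTURE)
  ca2 <- read_pdb(tie)[[1]]$atom
  ca2 <- ca2[ca2$elety == "CA", ]
  expect_equal(as.numeric(ca2[, c("x", "y", "z")]), c(0, 0, 0))
  # no duplicate atom names after resolution
  m2 <- read_pdb(ALTLOC_FIXTURE)[[1]]
  expect_false(any(duplicated(paste(m2$atom$reskey, m2$atom$elety))))
})

test_that("SSBOND records attach to every model and to CYS pairs only", {
  txt <- build_multimodel(2, bridge_spec())
  mods <- read_pdb(txt)
  expect_equal(nrow(mods[[1]]$ssbonds), 1)
  expect_equal(nrow(mods[[2]]$ssbonds), 1)
  # an SSBOND naming an absent residue is dropped with a warning
  bad <- c("SSBOND   1 CYS A   99    CYS A  100", ALTLOC_FIXTURE)
  expect_warning(m <- read_pdb(bad)[[1]], "SSBOND")
  expect_equal(nrow(m$ssbonds), 0)
})

test_that("selenomethionine parses as MET; hydrogens and other HETATM skipped", {
  txt <- pdb_lines(
    "ATOM      1  N   ALA A   1       1.458   0.000   0.000  1.00 10.00           N",
    "ATOM      2  HA  ALA A   1       1.000   1.000   0.000  1.00 10.00           H",
    "HETATM    3  CA  MSE A   2       3.000   0.000   0.000  1.00 11.00           C",
    "HETATM    4  SE  MSE A   2       4.000   1.000   0.000  1.00 11.00          SE",
    "HETATM    5  O   HOH A 100       9.000   9.000   9.000  1.00 30.00           O",
    "END")
  m <- read_pdb(txt)[[1]]
  expect_false(any(m$atom$elesy == "H"))
  expect_false(any(m$atom$resid == "HOH"))
  mse <- m$atom[m$atom$resno == 2, ]
  expect_true(all(mse$resid == "MET"))
  expect_true("SD" %in% mse$elety)   # SE renamed to the MET sulfur slot
})

test_that("parse errors are informative", {
  expect_error(read_pdb("REMARK nothing here\nEND"), "no coordinates")
  expect_error(read_pdb(""), "no coordinates")
  bad <- ALTLOC_FIXTURE
  bad[2] <- sub("   0.000   0.000   0.000", "   xx.xxx   0.000   0.000", bad[2])
  expect_error(read_pdb(bad), "line 2")
  expect_warning(
    read_pdb(sub(" 10.00  ", " -5.00  ", ALTLOC_FIXTURE[1:2])),
    "negative B-factor")
})

test_that("read-write round trip preserves the retained record set", {
  fx <- build_ideal_bridge(bridge_spec(bfactor_plan = "gradient"))
  m1 <- read_pdb(write_pdb(fx$model))[[1]]
  m2 <- read_pdb(write_pdb(m1))[[1]]
  expect_equal(nrow(m1$atom), nrow(fx$model$atom))
  expect_equal(m1$atom$elety, fx$model$atom$elety)
  expect_lt(max(abs(as.matrix(m1$atom[, c("x", "y", "z")]) -
                      as.matrix(fx$model$atom[, c("x", "y", "z")]))), 1e-3)
  expect_lt(max(abs(m1$atom$b - fx$model$atom$b)), 0.01 + 1e-9)
  expect_equal(m1$ssbonds, fx$model$ssbonds)
  # second pass is exactly idempotent
  expect_identical(write_pdb(m1), write_pdb(m2))
})

test_that("parser agrees with the bio3d reference reader on a real structure", {
  skip_if_not_installed("bio3d")
  path <- system.file("examples/1hel.pdb", package = "bio3d")
  ours <- read_pdb(path)[[1]]
  ref <- bio3d::read.pdb(path, verbose = FALSE)
  ref_ca <- ref$atom[ref$atom$elety == "CA" & ref$atom$type == "ATOM", ]
  our_ca <- ours$atom[ours$atom$elety == "CA", ]
  expect_equal(nrow(our_ca), nrow(ref_ca))
  expect_equal(our_ca$x, ref_ca$x, tolerance = 1e-9)
  expect_equal(our_ca$b, ref_ca$b, tolerance = 1e-9)
  expect_equal(our_ca$resno, ref_ca$resno)
  expect_equal(ours$resolution, 2.0, tolerance = 1e-9)
  expect_equal(nrow(ours$ssbonds), 4)
})

test_that("mutant export builds cysteines with modeled sulfurs and SSBOND records", {
  fx <- build_ideal_bridge(bridge_spec())
  # make the scan targets non-cysteine so this models a real mutation
  wt <- fx$model
  keep <- !(wt$atom$resid == "CYS" & wt$atom$elety == "SG")
  wt$atom <- wt$atom[keep, ]
  wt$atom$resid[wt$atom$resid == "CYS"] <- "SER"
  wt$ssbonds <- wt$ssbonds[0, ]
  preds <- scan_disulfides(wt)
  expect_equal(nrow(preds), 1)

  txt <- write_mutant_pdb(wt, preds)
  mut <- read_pdb(txt)[[1]]
  cys <- unique(mut$atom$reskey[mut$atom$resid == "CYS"])
  expect_setequal(cys, c(fx$truth$key_a, fx$truth$key_b))
  expect_equal(nrow(mut$ssbonds), 1)
  sg <- mut$atom[mut$atom$elety == "SG" & mut$atom$reskey == fx$truth$key_a, ]
  expect_equal(sg$o, 1.00)
  ca_b <- wt$atom[wt$atom$reskey == fx$truth$key_a & wt$atom$elety == "CA", "b"]
  expect_equal(sg$b, ca_b)
  expect_lt(vec_distance(as.numeric(sg[, c("x", "y", "z")]),
                         c(preds$sg_a_x, preds$sg_a_y, preds$sg_a_z)), 1e-3)
})

test_that("mutant export handles glycine, empty selections and bad references", {
  fx <- build_ideal_bridge(bridge_spec())
  model <- fx$model
  # empty prediction list writes the unmodified model byte-for-byte
  empty <- scan_disulfides(model, scan_config(cb_cb_range = c(0.1, 0.2)))
  expect_identical(write_mutant_pdb(model, empty), write_pdb(model))
  # glycine target: CB is constructed
  gly <- model
  drop <- gly$atom$reskey == fx$truth$key_a & gly$atom$elety %in% c("CB", "SG")
  gly$atom <- gly$atom[!drop, ]
  gly$atom$resid[gly$atom$reskey == fx$truth$key_a] <- "GLY"
  gly$ssbonds <- gly$ssbonds[0, ]
  preds <- scan_disulfides(gly)
  expect_equal(preds$aa1, "GLY")
  mut <- read_pdb(suppressWarnings(write_mutant_pdb(gly, preds)))[[1]]
  a <- mut$atom[mut$atom$reskey == fx$truth$key_a, ]
  expect_true(all(c("CB", "SG") %in% a$elety))
  expect_true(all(a$resid == "CYS"))
  # native cysteines are re-posed with one warning per residue
  preds2 <- scan_disulfides(model)
  w <- capture_warnings(write_mutant_pdb(model, preds2))
  expect_length(w, 2)
  expect_match(w, "re-posed", all = TRUE)
  # referencing a missing residue is a consistency error
  bad <- preds
  bad$res1 <- 999L
  expect_error(write_mutant_pdb(gly, bad), "absent")
})

make_preds <- function(n, sum_bfactor, energy = seq_len(n)) {
  if (n == 0L) return(make_preds(1L, 0)[0, ])
  structure(data.frame(
    chain1 = "A", res1 = seq_len(n), icode1 = "", aa1 = "ALA",
    chain2 = "A", res2 = seq_len(n) + 10L, icode2 = "", aa2 = "ALA",
    chi1_a = -60, chi1_b = -60, chi3 = -87, theta_a = 104.9, theta_b = 104.9,
    ss_distance = 2.04, e_chi1_a = 0, e_chi1_b = 0, e_chi3 = 0,
    e_angle_a = 0, e_angle_b = 0, energy = energy,
    sum_bfactor = sum_bfactor,
    sg_a_x = 0, sg_a_y = 0, sg_a_z = 0, sg_b_x = 0, sg_b_y = 0, sg_b_z = 0,
    is_native = FALSE, stringsAsFactors = FALSE),
    class = c("ss_predictions", "data.frame"))
}

test_that("CSV export sorts on any column with stable ties", {
  p <- make_preds(3, sum_bfactor = c(12.5, 30.25, 7))
  out <- predictions_csv(p, sort_by = "sum_bfactor", descending = TRUE)
  expect_equal(out[1],
               "chain1,res1,aa1,chain2,res2,aa2,chi3_deg,energy_kcal_mol,sum_bfactor")
  got <- read.csv(text = paste(out, collapse = "\n"))
  expect_equal(got$sum_bfactor, c(30.25, 12.5, 7.00))
  expect_equal(got$res1, c(2L, 1L, 3L))
  # ties keep the original scan order
  tie <- predictions_csv(make_preds(4, sum_bfactor = c(5, 5, 5, 5)),
                         sort_by = "sum_bfactor", descending = TRUE)
  expect_equal(read.csv(text = paste(tie, collapse = "\n"))$res1, 1:4)
  # 2-decimal formatting of angles and energies
  expect_match(out[2], ",-87.00,", fixed = TRUE)
  # empty input yields a header-only stream
  expect_length(predictions_csv(make_preds(0, numeric(0))), 1)
  expect_error(predictions_csv(p, sort_by = "nope"), "unknown sort column")
})

test_that("fetch_pdb validates identifiers and honors its disk cache", {
  expect_error(fetch_pdb("xx"), "invalid PDB identifier")
  expect_error(fetch_pdb("abcd"), "invalid PDB identifier")   # must start with digit
  expect_error(fetch_pdb("1ab"), "invalid PDB identifier")
  cache <- withr::local_tempdir()
  writeLines(ALTLOC_FIXTURE, file.path(cache, "9xyz.pdb"))
  # warm cache: no network needed even with an unreachable base URL
  got <- fetch_pdb("9xyz", cache_dir = cache,
                   base_url = "http://127.0.0.1:1/none")
  expect_identical(got, ALTLOC_FIXTURE)
  expect_length(read_pdb(got), 1)
  # cold cache + unreachable host is a clean retrieval error
  expect_error(fetch_pdb("9abc", cache_dir = cache,
                         base_url = "http://127.0.0.1:1/none"),
               "retrieval failed")
})
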
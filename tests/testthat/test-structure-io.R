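test_that("PDB parsing echoes residues and coordinates", {
  st <- parse_structure(tripeptide_pdb(), "pdb")
  expect_s3_class(st, "xl_structure")
  expect_equal(nrow(unique(st$atoms[c("chain", "resno")])), 3)
  expect_equal(unname(unlist(st$atoms[2, c("x", "y", "z")])),
               c(1.458, 0, 0))
  expect_equal(st$atoms$resname[st$atoms$resno == 2], "GLY")
})

test_that("only the first MODEL block is retained", {
  text <- c("MODEL        1",
            pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
            "ENDMDL",
            "MODEL        2",
            pdb_line(1, "CA", "ALA", "A", 1, 9, 9, 9),
            "ENDMDL", "END")
  st <- parse_structure(text, "pdb")
  expect_equal(nrow(st$atoms), 1)
  expect_equal(st$atoms$x, 0)
})

test_that("altlocs resolve to highest occupancy, ties alphabetical", {
  text <- c(pdb_line(1, "CA", "GLY", "A", 2, 3, 1, 0, occ = 0.4,
                     altloc = "A"),
            pdb_line(2, "CA", "GLY", "A", 2, 3.1, 1, 0, occ = 0.6,
                     altloc = "B"),
            pdb_line(3, "CB", "ALA", "A", 3, 0, 0, 0, occ = 0.5,
                     altloc = "B"),
            pdb_line(4, "CB", "ALA", "A", 3, 1, 0, 0, occ = 0.5,
                     altloc = "A"),
            "END")
  st <- parse_structure(text, "pdb")
  expect_equal(nrow(st$atoms), 2)
  expect_equal(st$atoms$x[st$atoms$resno == 2], 3.1)   # occ 0.6 wins
  expect_equal(st$atoms$x[st$atoms$resno == 3], 1)     # tie: altloc A wins
})

test_that("malformed and empty input raise informative parse errors", {
  bad <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0), "END")
  bad[1] <- sub("   0.000", "   xxxxx", bad[1])
  expect_error(parse_structure(bad, "pdb"), "line 1")
  expect_error(parse_structure("", "pdb"), "empty")
  expect_error(parse_structure(c("REMARK", "END"), "pdb"), "no ATOM")
})

test_that("minimal mmCIF atom_site loops parse to the same structure", {
  cif <- c("data_test", "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.auth_atom_id",
           "_atom_site.label_alt_id", "_atom_site.auth_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
           "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.pdbx_PDB_model_num",
           "ATOM 1 C CA . ALA A 1 ? 1.458 0.000 0.000 1.00 1",
           "ATOM 2 C CB . ALA A 1 ? 2.000 1.400 0.000 1.00 1",
           "ATOM 3 C CA . ALA A 1 ? 9.000 9.000 9.000 1.00 2",
           "#")
  st <- parse_structure(cif, "mmcif")
  expect_equal(nrow(st$atoms), 2)          # second model dropped
  expect_equal(st$atoms$x, c(1.458, 2.0))
  expect_equal(st$atoms$chain, c("A", "A"))
})

test_that("anchor coordinates follow the CB rule with the glycine exception", {
  st <- parse_structure(tripeptide_pdb(), "pdb")
  expect_equal(anchor_coordinate(st, residue_ref("A", 1)), c(2.0, 1.4, 0))
  expect_equal(anchor_coordinate(st, residue_ref("A", 2)), c(3, 1, 0))
  expect_error(anchor_coordinate(st, residue_ref("A", 3)), "no CB")
  expect_warning(
    ca <- anchor_coordinate(st, residue_ref("A", 3), fallback_ca = TRUE),
    "falling back")
  expect_equal(ca, c(6, 5, 0))
  expect_error(anchor_coordinate(st, residue_ref("A", 9)), "not found")
  expect_error(anchor_coordinate(st, residue_ref("A", 2, resname = "ALA")),
               "expected ALA")
})

test_that("pair distances are exact, order preserving and symmetric", {
  text <- c(pdb_line(1, "CB", "ALA", "A", 1, 0, 0, 0),
            pdb_line(2, "CB", "ALA", "A", 2, 3, 4, 0), "END")
  st <- parse_structure(text, "pdb")
  p12 <- list(list(residue_ref("A", 1), residue_ref("A", 2)))
  p21 <- list(list(residue_ref("A", 2), residue_ref("A", 1)))
  expect_equal(pair_distances(st, p12), 5)
  expect_equal(pair_distances(st, p21), 5)
  expect_equal(pair_distances(
    st, list(list(residue_ref("A", 1), residue_ref("A", 1)))), 0)
  expect_error(pair_distances(
    st, list(list(residue_ref("A", 1), residue_ref("A", 7)))), "pair 1")
})

test_that("pair distances match brute-force arithmetic and rigid invariance", {
  toy <- make_toy_complex(seed = 5)
  st <- toy$complex
  set.seed(5)
  pairs <- lapply(1:10, function(i)
    list(residue_ref("R", sample(30, 1)), residue_ref("A", sample(30, 1))))
  d <- pair_distances(st, pairs)
  oracle <- vapply(pairs, function(p) {
    a <- anchor_coordinate(st, p[[1]]); b <- anchor_coordinate(st, p[[2]])
    sqrt(sum((a - b)^2))
  }, numeric(1))
  expect_equal(d, oracle, tolerance = 1e-12)
  R <- random_rotation()
  moved <- set_coords(st, transform_coords(coords(st), R, c(3, -7, 11)))
  expect_equal(pair_distances(moved, pairs), d, tolerance = 1e-9)
})

test_that("superposition recovers planted transforms with det +1", {
  set.seed(1)
  X <- matrix(rnorm(30), 10, 3)
  fit0 <- superpose(X, X)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)

  Rz <- axis_rotation(c(0, 0, 1), 30)
  Y <- transform_coords(X, Rz, c(1, 2, 3))
  fit <- superpose(X, Y)
  expect_equal(fit$rotation, Rz, tolerance = 1e-8)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  # idempotence: re-superposing the fitted coordinates gives the identity
  fit2 <- superpose(transform_coords(X, fit$rotation, fit$translation), Y)
  expect_equal(fit2$rotation, diag(3), tolerance = 1e-8)

  # reflected target still yields a proper rotation
  Yr <- X %*% diag(c(-1, 1, 1))
  fitr <- superpose(X, Yr)
  expect_equal(det(fitr$rotation), 1, tolerance = 1e-10)
  expect_gt(fitr$rmsd, 0)

  expect_error(superpose(X[1:2, ], Y[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "degenerate")
})

test_that("superposition RMSD agrees with an independent implementation", {
  set.seed(2)
  X <- matrix(rnorm(45), 15, 3)
  Y <- transform_coords(X, random_rotation(), rnorm(3)) +
    matrix(rnorm(45, 0, 0.3), 15, 3)
  fit <- superpose(X, Y)
  ref <- bio3d::fit.xyz(fixed = as.vector(t(Y)), mobile = as.vector(t(X)),
                        fixed.inds = 1:45, mobile.inds = 1:45)
  rmsd_ref <- sqrt(mean(colSums(matrix(ref - as.vector(t(Y)), 3)^2)))
  expect_equal(fit$rmsd, rmsd_ref, tolerance = 1e-6)
})

test_that("PDB round trip preserves numbering and coordinates", {
  toy <- make_toy_complex(seed = 3)
  st <- toy$complex
  txt <- write_pdb(st)
  st2 <- parse_structure(txt, "pdb")
  expect_equal(st2$atoms$resno, st$atoms$resno)
  expect_equal(st2$atoms$chain, st$atoms$chain)
  expect_equal(coords(st2), coords(st), tolerance = 1e-3)
})

test_that("multi-model ensembles round trip and enforce shared topology", {
  toy <- make_toy_complex(seed = 3)
  tr <- simulate_trajectory(toy$receptor, toy$mobile, n_frames = 4, seed = 9)
  f <- tempfile(fileext = ".pdb")
  write_ensemble(tr$ensemble, f)
  ens <- read_ensemble(f)
  expect_equal(n_frames(ens), 4)
  expect_equal(ens$xyz, tr$ensemble$xyz, tolerance = 1e-3)
  # mismatched topology rejected
  bad <- c("MODEL        1", pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
           "ENDMDL", "MODEL        2",
           pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
           pdb_line(2, "CA", "ALA", "A", 2, 1, 0, 0),
           "ENDMDL", "END")
  expect_error(read_ensemble(text = bad), "topology")
})
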
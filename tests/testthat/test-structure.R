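test_that("PDB parsing round-trips a toy complex", {
  txt <- simulate_toy_structure(4, 3, seed = 2)
  s <- parse_structure(txt)
  expect_s3_class(s, "macro_structure")
  expect_setequal(s$chains$chain, c("A", "B"))
  expect_equal(s$chains$kind[s$chains$chain == "A"], "protein")
  expect_equal(s$chains$kind[s$chains$chain == "B"], "nucleic")
  expect_equal(sum(s$atoms$chain == "A"), 4 * 4)   # N, CA, C, O per residue
  expect_equal(sum(s$atoms$chain == "B"), 3 * 3)

  expect_equal(nrow(parse_structure("")$atoms), 0)
  expect_equal(nrow(parse_structure("REMARK nothing here")$atoms), 0)
})

test_that("blank element columns are inferred from atom names", {
  rec <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2 1HB  ALA A   1       1.000   0.000   0.000  1.00  0.00",
    "ATOM      3  N   ALA A   1       0.000   1.400   0.000  1.00  0.00")
  s <- parse_structure(rec)
  expect_equal(s$atoms$element, c("C", "H", "N"))
})

test_that("malformed records fail with the line number", {
  bad <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CB  ALA A   1       bad.xx   0.000   0.000  1.00  0.00")
  expect_error(parse_structure(bad), "line 2")
  expect_error(parse_structure("ATOM  truncated"), "line 1")
})

test_that("altloc groups collapse to the highest-occupancy conformer", {
  rec <- c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.70  0.00           C")
  s <- parse_structure(rec)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$x, 9)
})

test_that("planted contacts are recovered exactly, hydrogens ignored", {
  txt <- simulate_toy_structure(20, 10, planted_contacts = c(5, 17),
                                seed = 3, h_decoy = 9)
  s <- parse_structure(txt)
  cs <- find_dna_contacts(s, "A", "B", cutoff = 3.5)
  expect_equal(cs$resno, c(5, 17))
  expect_equal(brute_contacts(s, "A", "B", 3.5), c(5, 17))

  # no contacts planted, and a zero cutoff, both give the empty set
  s0 <- parse_structure(simulate_toy_structure(8, 4, seed = 4))
  expect_equal(nrow(find_dna_contacts(s0, "A", "B")), 0)
  expect_equal(nrow(find_dna_contacts(s, "A", "B", cutoff = 0)), 0)
  expect_error(find_dna_contacts(s, "Z", "B"), "unknown chain")
})

test_that("contact calls equal the brute-force oracle and grow with cutoff", {
  set.seed(9)
  for (i in 1:5) {
    n_res <- sample(5:25, 1)
    planted <- sample(seq_len(n_res), sample(0:3, 1))
    s <- parse_structure(simulate_toy_structure(n_res, 8,
                                                planted_contacts = planted,
                                                seed = i))
    prev <- integer(0)
    for (cutoff in c(2, 3.5, 6, 12, 25)) {
      got <- find_dna_contacts(s, "A", "B", cutoff)$resno
      expect_equal(got, brute_contacts(s, "A", "B", cutoff))
      expect_true(all(prev %in% got))        # monotone in cutoff
      prev <- got
    }
  }
})

test_that("contacts and burial survive rotation and translation", {
  txt <- simulate_toy_structure(12, 6, planted_contacts = c(3, 11), seed = 6)
  s <- parse_structure(txt)
  s2 <- transform_structure(s)
  expect_equal(find_dna_contacts(s2, "A", "B")$resno,
               find_dna_contacts(s, "A", "B")$resno)
  b1 <- classify_burial(s, "A", n_points = 200)
  b2 <- classify_burial(transform_structure(s), "A", n_points = 200)
  expect_lt(max(abs(b1$rel_sasa - b2$rel_sasa)), 0.05)
})

test_that("interchain contacts report the bridging residue only", {
  # two protein chains 30 A apart except one bridging residue
  mk <- function(chain, xoff, n) {
    unlist(lapply(seq_len(n), function(i) {
      perturbpheno:::format_pdb_atom(i, "CA", "GLY", chain, i,
                                     xoff + i * 3.8, 0, 0, "C")
    }))
  }
  # chain C shifted 30 A in z; residue 3 of A reaches across via CB
  lines <- c(mk("A", 0, 5),
             vapply(seq_len(5), function(i) {
               perturbpheno:::format_pdb_atom(10 + i, "CA", "GLY", "C", i,
                                              i * 3.8, 0, 30, "C")
             }, character(1)),
             perturbpheno:::format_pdb_atom(99, "CB", "GLY", "A", 3,
                                            3 * 3.8, 0, 27.5, "C"))
  s <- parse_structure(lines)
  cs <- find_interchain_contacts(s, "A", "C", cutoff = 3.5)
  expect_equal(cs$resno, 3)
  expect_equal(nrow(find_interchain_contacts(s, "C", "A", cutoff = 1)), 0)
  expect_error(find_interchain_contacts(s, "A", "A"), "differ")
  # atom order within the file does not matter (set semantics)
  s_shuf <- s
  s_shuf$atoms <- s_shuf$atoms[rev(seq_len(nrow(s_shuf$atoms))), ]
  expect_equal(find_interchain_contacts(s_shuf, "A", "C", 3.5)$resno, 3)
})

test_that("burial classes respond to occlusion", {
  # a single isolated residue is fully exposed -> surface
  iso <- parse_structure(perturbpheno:::format_pdb_atom(
    1, "CA", "ALA", "A", 1, 0, 0, 0, "C"))
  expect_equal(classify_burial(iso, "A")$class, "surface")

  # a residue enclosed in a dense synthetic shell -> core
  shell_pts <- perturbpheno:::sphere_points(80) * 4
  lines <- c(perturbpheno:::format_pdb_atom(1, "CA", "GLY", "A", 1,
                                            0, 0, 0, "C"),
             vapply(seq_len(nrow(shell_pts)), function(i) {
               perturbpheno:::format_pdb_atom(1 + i, "CA", "GLY", "A", 1 + i,
                                              shell_pts[i, 1],
                                              shell_pts[i, 2],
                                              shell_pts[i, 3], "C")
             }, character(1)))
  enc <- parse_structure(lines)
  b <- classify_burial(enc, "A")
  expect_equal(b$class[b$resno == 1], "core")
  expect_lt(b$rel_sasa[b$resno == 1], 0.02)

  # unknown residue name is flagged intermediate
  unk <- parse_structure(c(
    perturbpheno:::format_pdb_atom(1, "CA", "ALA", "A", 1, 0, 0, 0, "C"),
    perturbpheno:::format_pdb_atom(2, "C1", "MSE", "A", 2, 8, 0, 0, "C")))
  expect_warning(bu <- classify_burial(unk, "A"), "reference")
  expect_equal(bu$class[bu$resname == "MSE"], "intermediate")
  expect_true(bu$flagged[bu$resname == "MSE"])
})

test_that("burial classes are stable in the sphere-point count", {
  s <- parse_structure(simulate_toy_structure(10, 4, seed = 12))
  b100 <- classify_burial(s, "A", n_points = 100)
  b960 <- classify_burial(s, "A", n_points = 960)
  off_threshold <- abs(b100$rel_sasa - 0.05) > 0.03 &
    abs(b100$rel_sasa - 0.25) > 0.03
  expect_equal(b100$class[off_threshold], b960$class[off_threshold])
})
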
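two_residue_structure <- function(d) {
  # one Ala per chain; CB atoms exactly d apart, CA atoms d + 3 apart
  structure_model(data.frame(
    chain = rep(c("A", "B"), each = 2),
    resno = 1L,
    resid = "ALA",
    elety = rep(c("CA", "CB"), 2),
    x = 0,
    y = c(-1.5, 0, d + 1.5, d),
    z = 0, stringsAsFactors = FALSE))
}

test_that("pair distances report side-chain minima and NA for missing atoms", {
  s <- two_residue_structure(7.3)
  ct <- pair_distances(s, "A", "B")
  expect_s3_class(ct, "contact_table")
  expect_equal(ct$d_sc, 7.3)
  expect_equal(ct$d_cb, 7.3)
  expect_equal(ct$d_ca, 7.3 + 3)
  # symmetric in argument order
  ct2 <- pair_distances(s, "B", "A")
  expect_equal(ct2$d_sc, ct$d_sc)

  # coincident atoms give zero
  s0 <- two_residue_structure(0)
  expect_equal(pair_distances(s0, "A", "B")$d_sc, 0)

  # residue stripped of side-chain atoms -> absent, not zero
  s$atoms <- s$atoms[!(s$atoms$chain == "B" & s$atoms$elety == "CB"), ]
  ct3 <- pair_distances(s, "A", "B")
  expect_true(is.na(ct3$d_sc))
  expect_false(is.na(ct3$d_ca))
})

test_that("chain contact uses an inclusive 12 Angstrom Calpha rule", {
  expect_true(protein_pair_in_contact(two_residue_structure(5), "A", "B"))
  expect_false(protein_pair_in_contact(two_residue_structure(50), "A", "B"))
  # boundary: CA-CA distance exactly 12.0 counts as contact
  s <- two_residue_structure(9)
  expect_true(protein_pair_in_contact(s, "A", "B"))
  expect_false(protein_pair_in_contact(s, "A", "B", d_cut = 11.9))
})

test_that("toy structures realize requested contact geometry", {
  contacts <- data.frame(res_a = c(2, 5, 8), res_b = c(3, 6, 9),
                         distance = 6)
  s <- make_toy_structure(len_a = 10, len_b = 10, contacts = contacts,
                          separation = 50)
  ct <- pair_distances(s, "A", "B")
  for (k in 1:3) {
    hit <- ct[ct$resno_a == contacts$res_a[k] &
                ct$resno_b == contacts$res_b[k], ]
    expect_equal(hit$d_sc, 6, tolerance = 0.1)
  }
  # all non-contact residue pairs stay far
  other <- ct[!(paste(ct$resno_a, ct$resno_b) %in%
                  paste(contacts$res_a, contacts$res_b)), ]
  expect_gt(min(other$d_sc), 7)
  # empty contact list: chains fully separated; generator is deterministic
  s_far <- make_toy_structure(len_a = 4, len_b = 4, separation = 40)
  expect_gt(min(pair_distances(s_far, "A", "B")$d_sc), 35)
  expect_identical(make_toy_structure(contacts = contacts),
                   make_toy_structure(contacts = contacts))
  expect_error(make_toy_structure(contacts = data.frame(
    res_a = 1, res_b = 1, distance = 60), separation = 50), "infeasible")
})

test_that("precision curve bins scored pairs against structure distances", {
  contacts <- data.frame(res_a = 1:2, res_b = 1:2, distance = 5)
  s <- make_toy_structure(len_a = 3, len_b = 3, contacts = contacts,
                          separation = 60)
  ct <- pair_distances(s, "A", "B")
  df <- data.frame(i = c(1L, 2L, 3L), j = c(4L, 5L, 6L),
                   resno_i = 1:3, resno_j = 1:3,
                   chain_i = "A", chain_j = "B", s = 1, s_corr = 1,
                   ncs = c(3, 2.5, 0.2),
                   score = c(0.9, 0.85, 0.1),
                   inter = TRUE, stringsAsFactors = FALSE)
  sc <- fake_scores(df, boundary = 3L, N = 50, L = 6L)
  pc <- precision_curve(sc, ct, breaks = c(0, 0.5, 1), contact_cut = 12)
  expect_equal(pc$n, c(1L, 2L))
  expect_equal(pc$precision, c(0, 1))   # hand count
  # empty bin reported as missing
  pc2 <- precision_curve(sc, ct, breaks = c(0, 0.5, 0.95, 1))
  expect_equal(pc2$n[3], 0L)
  expect_true(is.na(pc2$precision[3]))
  # all predicted pairs in contact
  sc_all <- fake_scores(df[1:2, ], boundary = 3L, N = 50, L = 6L)
  pc3 <- precision_curve(sc_all, ct, breaks = c(0, 1))
  expect_equal(pc3$precision, 1)
})

test_that("fnat is 1 for self, 0 for separated or broken interfaces", {
  contacts <- data.frame(res_a = c(2, 4, 6), res_b = c(2, 4, 6),
                         distance = 4.5)
  ref <- make_toy_structure(len_a = 8, len_b = 8, contacts = contacts)
  expect_equal(fnat(ref, ref), 1.0)

  apart <- ref
  bsel <- apart$atoms$chain == "B"
  apart$atoms$y[bsel] <- apart$atoms$y[bsel] + 100
  expect_equal(fnat(apart, ref), 0.0)
  expect_error(fnat(ref, apart), "no interface contacts")

  # single native contact, broken in the model
  ref1 <- make_toy_structure(len_a = 4, len_b = 4,
                             contacts = data.frame(res_a = 2, res_b = 2,
                                                   distance = 4.0))
  mod1 <- make_toy_structure(len_a = 4, len_b = 4,
                             contacts = data.frame(res_a = 2, res_b = 2,
                                                   distance = 9.0))
  expect_equal(fnat(mod1, ref1), 0.0)
  expect_equal(fnat(ref1, ref1), 1.0)
})

test_that("interface RMSD is zero for self and invariant to rigid motion", {
  contacts <- data.frame(res_a = c(2, 4, 6), res_b = c(2, 4, 6),
                         distance = 6)
  ref <- make_toy_structure(len_a = 8, len_b = 8, contacts = contacts)
  expect_equal(interface_rmsd(ref, ref), 0, tolerance = 1e-9)
  moved <- rigid_move(ref)
  expect_lt(abs(interface_rmsd(moved, ref)), 1e-6)
})

test_that("interface RMSD matches an independent superposition oracle", {
  contacts <- data.frame(res_a = c(2, 4, 6), res_b = c(2, 4, 6),
                         distance = 6)
  ref <- make_toy_structure(len_a = 8, len_b = 8, contacts = contacts)
  model <- ref
  bsel <- model$atoms$chain == "B"
  model$atoms$x[bsel] <- model$atoms$x[bsel] + 2   # displace one chain 2 A

  got <- interface_rmsd(model, ref)
  # oracle: identify interface residues from the reference, superpose with
  # bio3d least squares, compute RMSD
  ct <- pair_distances(ref, "A", "B")
  ifc <- ct[ct$d_ca <= 12, ]
  sel <- rbind(data.frame(chain = "A", resno = unique(ifc$resno_a)),
               data.frame(chain = "B", resno = unique(ifc$resno_b)))
  grab <- function(s) as.matrix(merge(sel, s$atoms[s$atoms$elety == "CA", ],
                                      sort = FALSE)[, c("x", "y", "z")])
  want <- bio3d_superpose_rmsd(grab(ref), grab(model))
  expect_equal(got, want, tolerance = 1e-6)
  expect_gt(got, 0.5)  # a 2 A displacement cannot be superposed away
})

test_that("structures round-trip through PDB files", {
  contacts <- data.frame(res_a = 2, res_b = 3, distance = 5)
  s <- make_toy_structure(len_a = 4, len_b = 4, contacts = contacts)
  path <- tempfile(fileext = ".pdb")
  write_structure(s, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(s$atoms))
  ct1 <- pair_distances(s, "A", "B")
  ct2 <- pair_distances(back, "A", "B")
  expect_equal(ct2$d_sc, ct1$d_sc, tolerance = 1e-3)
})
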
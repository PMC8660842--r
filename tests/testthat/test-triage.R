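# Tanimoto similarity, strict probability threshold, error explanation.

test_that("tanimoto handles identity, disjointness and the empty case", {
  expect_equal(tanimoto(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(tanimoto(c(1, 0, 0), c(0, 1, 1)), 0)
  a <- numeric(8); a[c(1, 2, 3)] <- 1
  b <- numeric(8); b[c(2, 3, 4)] <- 1
  expect_equal(tanimoto(a, b), 0.5)   # 2 shared / 4 union
  expect_equal(tanimoto(numeric(4), numeric(4)), 1)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")
})

test_that("the probability threshold is strict", {
  preds <- data.frame(mol_id = c("a", "b", "c", "d"),
                      predicted = c("POS", "NEG", "NEG", "POS"),
                      probability = c(0.95, 0.85, 0.80, 0.81))
  truth <- data.frame(mol_id = c("a", "b", "c", "d"),
                      label = c("POS", "POS", "POS", "NEG"))
  ent <- highConfidenceErrors(preds, truth, p_threshold = 0.8)
  # a: correct -> excluded; b: FN 0.85 in; c: FN at exactly 0.80 out;
  # d: FP 0.81 in
  expect_setequal(ent$mol_id, c("b", "d"))
  expect_identical(ent$error_type[ent$mol_id == "b"], "FN")
  expect_identical(ent$error_type[ent$mol_id == "d"], "FP")
})

test_that("explanations pick up quality flags and neighbour conflicts", {
  train_fp <- new("FeatureMatrix",
                  values = matrix(c(1, 1, 1, 0, 0, 0, 0, 0,
                                    1, 1, 0, 0, 0, 0, 0, 1,
                                    0, 0, 0, 0, 1, 1, 1, 1),
                                  3, 8, byrow = TRUE,
                                  dimnames = list(c("t1", "t2", "t3"),
                                                  sprintf("b%d", 1:8))),
                  provenance = "Morgan", dropped = character(0))
  query_fp <- new("FeatureMatrix",
                  values = matrix(c(1, 1, 1, 0, 0, 0, 0, 0),
                                  1, 8, dimnames = list("q1",
                                                        sprintf("b%d", 1:8))),
                  provenance = "Morgan", dropped = character(0))
  labels <- data.frame(mol_id = "q1", label = "POS",
                       quality_flags = "near_lower_endpoint")
  train_labels <- data.frame(mol_id = c("t1", "t2", "t3"),
                             label = c("NEG", "POS", "POS"))
  ent <- data.frame(mol_id = "q1", error_type = "FN", probability = 0.9)
  tri <- explainErrors(ent, labels, query_fp, train_fp, train_labels,
                       k_neighbors = 2)
  reasons <- splitFlagsT(tri$reasons)
  # t1 is identical (sim 1.0) and NEG = the wrong prediction -> conflict
  expect_true("training_neighbor_conflict" %in% reasons)
  expect_true("near_lower_endpoint" %in% reasons)
  nb <- splitFlagsT(tri$neighbor_ids)
  expect_identical(nb[1], "t1")
  sims <- as.numeric(splitFlagsT(tri$neighbor_sims))
  expect_true(all(diff(sims) <= 0))  # nonincreasing
  expect_length(nb, 2)
})

test_that("errors with no firing rule come back unexplained", {
  train_fp <- new("FeatureMatrix",
                  values = matrix(c(0, 0, 1, 1), 1, 4,
                                  dimnames = list("t1", sprintf("b%d", 1:4))),
                  provenance = "Morgan", dropped = character(0))
  query_fp <- new("FeatureMatrix",
                  values = matrix(c(1, 1, 0, 0), 1, 4,
                                  dimnames = list("q1", sprintf("b%d", 1:4))),
                  provenance = "Morgan", dropped = character(0))
  labels <- data.frame(mol_id = "q1", label = "POS", quality_flags = "")
  train_labels <- data.frame(mol_id = "t1", label = "POS")
  ent <- data.frame(mol_id = "q1", error_type = "FN", probability = 0.9)
  tri <- explainErrors(ent, labels, query_fp, train_fp, train_labels)
  expect_identical(tri$reasons, "unexplained")
})

test_that("self-matches are excluded from the neighbour list", {
  vals <- matrix(c(1, 1, 0, 0,
                   1, 0, 1, 0), 2, 4, byrow = TRUE,
                 dimnames = list(c("q1", "t1"), sprintf("b%d", 1:4)))
  both <- new("FeatureMatrix", values = vals, provenance = "Morgan",
              dropped = character(0))
  labels <- data.frame(mol_id = "q1", label = "POS", quality_flags = "")
  train_labels <- data.frame(mol_id = c("q1", "t1"),
                             label = c("POS", "NEG"))
  ent <- data.frame(mol_id = "q1", error_type = "FN", probability = 0.9)
  tri <- explainErrors(ent, labels, both, both, train_labels,
                       k_neighbors = 1)
  expect_identical(splitFlagsT(tri$neighbor_ids), "t1")
})
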
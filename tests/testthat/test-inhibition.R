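test_that("pair weights follow exp(-d/lambda) with the infinite limit", {
  sp <- space_constant(lambda_um = 50)
  expect_equal(pair_weight(0, sp), 1, ignore_attr = TRUE)
  expect_equal(pair_weight(50e3, sp), exp(-1), ignore_attr = TRUE)
  sp_inf <- space_constant(lambda_um = Inf)
  expect_equal(pair_weight(1e9, sp_inf), 1, ignore_attr = TRUE)
  expect_error(space_constant(lambda_um = -2), "lambda must be > 0")
  # metric mismatch is caught
  D <- matrix(1); attr(D, "metric") <- "electrotonic"
  expect_error(pair_weight(D, sp), "does not match")
})

test_that("lambda and k weights agree through the conversion ratio", {
  ratio <- 4.48e-4
  sp_l <- space_constant(lambda_um = 50)
  sp_k <- space_constant(lambda_um = 50, conversion_ratio_m12 = ratio,
                         mode = "electrotonic")
  d_nm <- 30e3                      # 30 um real distance
  # electrotonic distance corresponding to d under the whole-skeleton ratio,
  # expressed in the internal nm^(1/2) scale
  d_e_nm12 <- (d_nm * 1e-9 / ratio) / sqrt(1e-9)
  expect_equal(pair_weight(d_nm, sp_l), pair_weight(d_e_nm12, sp_k),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("inhibition matrix equals the naive double sum", {
  toy <- make_toy_skeleton(n_neurites = 1, seed = 13)
  gen <- make_synthetic_synapses(toy, n_kc = 6, n_in = 12, n_out = 12,
                                 sigma_um = 15, seed = 13)
  m <- map_synapses(toy$skeleton, gen$synapses)
  out <- m[m$direction == "KC_to_APL", ]
  inp <- m[m$direction == "APL_to_KC", ]
  D <- pairwise_distances(toy$skeleton, out, inp, "real")
  s <- compute_inhibition_matrix(D, out$kc_id, inp$kc_id,
                                 space_constant(lambda_um = 50))
  ora <- oracle_inhibition(D, out$kc_id, inp$kc_id, 50)
  expect_equal(s, ora[rownames(s), colnames(s)], ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("single-pair and infinite-lambda closed forms hold", {
  skel <- chain_skeleton(c(1e3, 1e3), c(1, 1, 1))
  out <- manual_locations(skel, 1, 200, ids = 1)
  out$kc_id <- "KC1"
  inp <- manual_locations(skel, 2, 700, ids = 2)
  inp$kc_id <- "KC2"
  D <- pairwise_distances(skel, out, inp, "real")
  d <- 1e3 - 200 + 700
  s <- compute_inhibition_matrix(D, "KC1", "KC2",
                                 space_constant(lambda_um = 50))
  expect_equal(s["KC1", "KC2"], exp(-d / 50e3))

  # lambda = Inf: s(k1,k2) = (#outputs of k1) x (#inputs of k2)
  toy <- make_toy_skeleton(n_neurites = 1, seed = 17)
  gen <- make_synthetic_synapses(toy, n_kc = 5, n_in = 7, n_out = 4,
                                 seed = 17)
  m <- map_synapses(toy$skeleton, gen$synapses)
  o <- m[m$direction == "KC_to_APL", ]; i <- m[m$direction == "APL_to_KC", ]
  D2 <- pairwise_distances(toy$skeleton, o, i, "real")
  s_inf <- compute_inhibition_matrix(D2, o$kc_id, i$kc_id,
                                     space_constant(lambda_um = Inf))
  expect_equal(s_inf, matrix(4 * 7, 5, 5), ignore_attr = TRUE)
  # row sums: #outputs(k1) x total inputs
  expect_equal(unname(rowSums(s_inf)), rep(4 * 7 * 5, 5))
})

test_that("s is scale covariant: distances x c with lambda x c is invariant", {
  set.seed(19)
  D <- matrix(runif(30, 0, 1e5), 5, 6)
  src <- sample(c("a", "b"), 5, replace = TRUE)
  tgt <- sample(c("a", "b"), 6, replace = TRUE)
  s1 <- compute_inhibition_matrix(D, src, tgt, space_constant(lambda_um = 50))
  s2 <- compute_inhibition_matrix(D * 3, src, tgt,
                                  space_constant(lambda_um = 150))
  expect_equal(s1, s2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("kc metadata roster is enforced and zero-synapse KCs kept", {
  D <- matrix(1e3, 2, 2)
  expect_error(compute_inhibition_matrix(D, c("a", "b"), c("a", "b"),
                                         space_constant(lambda_um = 50),
                                         kc_ids = c("a")),
               "absent from metadata: b")
  s <- compute_inhibition_matrix(D, c("a", "b"), c("a", "b"),
                                 space_constant(lambda_um = 50),
                                 kc_ids = c("a", "b", "c"))
  expect_equal(dim(s), c(3, 3))
  expect_equal(unname(s["c", ]), rep(0, 3))
})

test_that("self/other ratio matches the two-KC closed form", {
  # KC1 and KC2 each have one co-located reciprocal pair, D apart
  skel <- chain_skeleton(c(100e3), c(1, 1))
  loc <- manual_locations(skel, c(1, 1, 1, 1), c(0, 0, 60e3, 60e3),
                          ids = 1:4)
  out <- loc[c(1, 3), ]; out$kc_id <- c("KC1", "KC2")
  inp <- loc[c(2, 4), ]; inp$kc_id <- c("KC1", "KC2")
  D <- pairwise_distances(skel, out, inp, "real")
  lam <- 50
  s <- compute_inhibition_matrix(D, out$kc_id, inp$kc_id,
                                 space_constant(lambda_um = lam))
  r <- self_other_ratio(s)
  expect_equal(r$ratios$ratio, rep(exp(60 / lam), 2), tolerance = 1e-10)

  # identical synapse sets for all KCs: every ratio 1
  out2 <- loc[c(1, 1, 1), ]; out2$kc_id <- c("a", "b", "c")
  inp2 <- loc[c(2, 2, 2), ]; inp2$kc_id <- c("a", "b", "c")
  D2 <- pairwise_distances(skel, out2, inp2, "real")
  s2 <- compute_inhibition_matrix(D2, out2$kc_id, inp2$kc_id,
                                  space_constant(lambda_um = lam))
  expect_equal(self_other_ratio(s2)$ratios$ratio, rep(1, 3))

  # lambda = Inf with equal input counts: ratio 1 exactly
  s3 <- compute_inhibition_matrix(D2, out2$kc_id, inp2$kc_id,
                                  space_constant(lambda_um = Inf))
  expect_equal(self_other_ratio(s3)$ratios$ratio, rep(1, 3))
})

test_that("singleton subtype groups are excluded with a warning", {
  s <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(r <- self_other_ratio(s, "same_subtype",
                                       subtype = c("x", "x", "y")),
                 "singleton")
  expect_equal(r$n_excluded, 1)
  expect_true(is.na(r$ratios$ratio[3]))
})

test_that("display order keeps subtypes contiguous and is stable", {
  set.seed(23)
  # block-structured matrix: two subtypes of three KCs
  s <- rbind(cbind(matrix(5, 3, 3), matrix(0, 3, 3)),
             cbind(matrix(0, 3, 3), matrix(5, 3, 3))) +
    matrix(runif(36, 0, 0.1), 6)
  dimnames(s) <- list(paste0("k", 1:6), paste0("k", 1:6))
  st <- rep(c("A", "B"), each = 3); names(st) <- rownames(s)
  ord <- order_kcs_for_display(s, subtype = st)
  expect_setequal(ord, rownames(s))
  expect_equal(unname(st[ord]), rep(c("A", "B"), each = 3))
  # identical rows: input order preserved
  s2 <- matrix(1, 4, 4, dimnames = list(paste0("k", 1:4), paste0("k", 1:4)))
  expect_equal(order_kcs_for_display(s2, subtype = rep("A", 4)),
               paste0("k", 1:4))
})
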
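test_that("enumerate_cases yields the 16-case Cartesian product, stably", {
  cases <- enumerate_cases()
  expect_equal(nrow(cases), 16L)
  key <- with(cases, paste(order_pref, border_regroup,
                           charge_extreme, hydro_extreme))
  expect_equal(anyDuplicated(key), 0L)
  # every axis is balanced 8/8 (product structure)
  for (axis in c("order_pref", "border_regroup", "charge_extreme",
                 "hydro_extreme"))
    expect_true(all(table(cases[[axis]]) == 8L))
  # the headline combination is present: ordered region, lower charge,
  # higher hydrophobicity, border regrouped as disordered
  expect_true(any(cases$order_pref == "O" & cases$charge_extreme == "min" &
                  cases$hydro_extreme == "max" & cases$border_regroup == "D"))
  expect_identical(cases, enumerate_cases())  # repeated calls identical
})

test_that("representative DE selection follows the case semantics", {
  ctx <- make_contexts("P", starts = c(5L, 20L, 40L),
                       H = c(1.0, 5.0, 2.0), C = c(-2, 0, -4),
                       order_class = c("O", "O", "D"))
  case <- data.frame(order_pref = "O", border_regroup = "D",
                     charge_extreme = "min", hydro_extreme = "max")
  sel <- select_representative_de(ctx, case)
  expect_equal(sel$start, 5L)          # the (O, C=-2, H=1.0) motif
  expect_equal(sel$order_indicator, 1L)
  expect_false(sel$fallback)

  # fallback: nothing in the preferred class -> extreme over all motifs
  ctx_d <- make_contexts("P", c(1L, 9L), H = c(0, 1), C = c(2, -1),
                         order_class = c("D", "D"))
  sel2 <- select_representative_de(ctx_d, case)
  expect_true(sel2$fallback)
  expect_equal(sel2$start, 9L)         # min charge among all
  expect_equal(sel2$order_indicator, 0L)

  # ties on charge and hydrophobicity -> smallest start wins
  ctx_tie <- make_contexts("P", c(30L, 4L), H = c(1, 1), C = c(0, 0),
                           order_class = c("O", "O"))
  expect_equal(select_representative_de(ctx_tie, case)$start, 4L)

  expect_error(select_representative_de(ctx[0, ], case), "empty")
})

test_that("selection agrees with brute force over random toys x all cases", {
  set.seed(11)
  cases <- enumerate_cases()
  for (rep in 1:40) {
    k <- sample(1:5, 1)
    ctx <- make_contexts("P", starts = sort(sample(0:60, k)),
                         H = round(stats::runif(k, -10, 10), 1),
                         C = sample(-4:4, k, replace = TRUE),
                         order_class = sample(c("O", "D", "B"), k,
                                              replace = TRUE))
    for (i in seq_len(nrow(cases))) {
      sel <- select_representative_de(ctx, cases[i, ])
      expect_equal(sel$start, ctx$start[oracle_select_idx(ctx, cases[i, ])],
                   label = paste("case", i, "rep", rep))
      # selected motif is always a member of the protein's context set
      expect_true(sel$start %in% ctx$start)
    }
  }
})

test_that("design matrices have one row per protein and react to cases", {
  d <- gen_protein_dataset(protein_gen_config(n_proteins = 10, seed = 5))
  ctx <- annotate_dataset(d)
  dm <- build_design_matrix(ctx, 1)
  expect_equal(nrow(dm), 10L)
  expect_setequal(dm$protein_id, dataset_ids(d))
  expect_true(all(dm$label %in% 0:1))

  # single-DE proteins select identically under every case
  d1 <- gen_protein_dataset(protein_gen_config(n_proteins = 8, de_count = 1,
                                               seed = 6))
  ctx1 <- annotate_dataset(d1)
  multi <- names(which(table(ctx1$protein_id) > 1))  # accidental extra DEs
  ctx1 <- ctx1[!ctx1$protein_id %in% multi, ]
  sels <- lapply(1:16, function(cid)
    build_design_matrix(ctx1, cid)$selected_start)
  for (cid in 2:16) expect_identical(sels[[cid]], sels[[1]])

  # with multi-DE proteins, two cases differing in charge extreme must
  # differ only on proteins holding more than one DE
  ctx5 <- rbind(
    make_contexts("A", c(1L, 10L), H = c(0, 0), C = c(-3, 3), c("O", "O")),
    make_contexts("B", 2L, H = 1, C = 0, "O"),
    make_contexts("C", c(3L, 12L), H = c(2, 2), C = c(-1, 2), c("O", "O"),
                  label = "non_secretory"),
    make_contexts("D", 4L, H = 0, C = 1, "D", label = "non_secretory"),
    make_contexts("E", 5L, H = -1, C = -1, "O"))
  case_min <- data.frame(order_pref = "O", border_regroup = "D",
                         charge_extreme = "min", hydro_extreme = "max")
  case_max <- transform(case_min, charge_extreme = "max")
  s_min <- build_design_matrix(ctx5, case_min)
  s_max <- build_design_matrix(ctx5, case_max)
  single <- c("B", "D", "E")
  expect_identical(s_min[s_min$protein_id %in% single, ],
                   s_max[s_max$protein_id %in% single, ])
  expect_false(identical(s_min$selected_start, s_max$selected_start))
})

test_that("extreme features are the per-protein extrema over DE contexts", {
  ctx <- make_contexts("P", c(0L, 5L, 9L), H = c(2, -1, 0),
                       C = c(-2, 0, 1), order_class = c("O", "D", "B"))
  ex <- extreme_features(ctx)
  expect_equal(ex$min_charge, -2)
  expect_equal(ex$max_charge, 1)
  expect_equal(ex$min_hydro, -1)
  expect_equal(ex$max_hydro, 2)

  one <- extreme_features(ctx[2, ])
  expect_equal(one$min_charge, one$max_charge)
  expect_equal(one$min_hydro, one$max_hydro)
  expect_error(extreme_features(ctx[0, ]), "empty")

  # brute force on a random 4-motif protein
  set.seed(13)
  ctx4 <- make_contexts("Q", 0:3 * 7L, H = stats::runif(4, -5, 5),
                        C = sample(-3:3, 4), order_class = rep("O", 4))
  ex4 <- extreme_features(ctx4)
  expect_equal(ex4$min_hydro, min(sapply(1:4, function(i) ctx4$H[i])))
  expect_equal(ex4$max_charge, max(sapply(1:4, function(i) ctx4$C[i])))
})
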
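two_disease_design <- function(seed = 1L, planted = NULL) {
  diseases <- data.frame(disease_id = c("DA", "DB"),
                         n_case = 15L, n_control = 15L)
  simulation_design(100L, diseases, planted, seed = seed)
}

test_that("simulate_expression is deterministic and honours a null design", {
  d <- two_disease_design()
  sim1 <- simulate_expression(d)
  sim2 <- simulate_expression(d)
  expect_identical(sim1$datasets$DA$values, sim2$datasets$DA$values)
  expect_identical(sim1$datasets$DB$values, sim2$datasets$DB$values)
  expect_length(sim1$truth$sets$DA$up, 0L)
  expect_length(sim1$truth$sets$DA$down, 0L)

  other <- simulate_expression(two_disease_design(seed = 2L))
  expect_false(identical(sim1$datasets$DA$values, other$datasets$DA$values))
})

test_that("adding a cohort does not reshuffle earlier cohorts", {
  d2 <- two_disease_design()
  d3 <- simulation_design(100L,
                          data.frame(disease_id = c("DA", "DB", "DC"),
                                     n_case = 15L, n_control = 15L),
                          seed = 1L)
  s2 <- simulate_expression(d2)
  s3 <- simulate_expression(d3)
  expect_identical(s2$datasets$DA$values, s3$datasets$DA$values)
  expect_identical(s2$datasets$DB$values, s3$datasets$DB$values)
})

test_that("planted shifts land within sampling error of the effect size", {
  planted <- data.frame(gene = c("G00001", "G00002"),
                        disease = "DA", direction = c("up", "down"))
  d <- two_disease_design(planted = planted)
  sim <- simulate_expression(d)
  ds <- sim$datasets$DA
  fc <- row_t_test(ds$values, ds$groups)$logfc
  names(fc) <- rownames(ds$values)
  se2 <- 2 * d$noise_sd * sqrt(2 / 15)   # two standard errors
  expect_lt(abs(fc["G00001"] - 2), se2)
  expect_lt(abs(fc["G00002"] + 2), se2)
  expect_equal(sim$truth$sets$DA$up, "G00001")
  expect_equal(sim$truth$sets$DA$down, "G00002")
})

test_that("design validation rejects out-of-range planting and tiny groups", {
  expect_error(two_disease_design(planted = data.frame(
    gene = "G99999", disease = "DA", direction = "up")), "outside")
  expect_error(simulation_design(10L,
                                 data.frame(disease_id = "DA", n_case = 2L,
                                            n_control = 15L)),
               "at least 3")
})

test_that("ground-truth pair stats agree exactly with the set operators", {
  planted <- plant_membership(c("DA", "DB", "DC"), sprintf("G%05d", 1:100),
                              n_up = 10L, n_down = 10L, n_shared_up = 4L,
                              n_shared_down = 3L, seed = 5L)
  d <- simulation_design(100L,
                         data.frame(disease_id = c("DA", "DB", "DC"),
                                    n_case = 15L, n_control = 15L),
                         planted, seed = 5L)
  truth <- simulate_expression(d)$truth
  sets <- truth$sets
  for (i in seq_len(nrow(truth$pair_stats))) {
    row <- truth$pair_stats[i, ]
    gi <- if (row$direction == "combined")
      union(sets[[row$disease_i]]$up, sets[[row$disease_i]]$down) else
        sets[[row$disease_i]][[row$direction]]
    gj <- if (row$direction == "combined")
      union(sets[[row$disease_j]]$up, sets[[row$disease_j]]$down) else
        sets[[row$disease_j]][[row$direction]]
    expect_identical(row$n_shared, shared_gene_count(gi, gj))
    expect_identical(row$jaccard, jaccard_score(gi, gj))
  }
  # the planting helper guarantees the focal overlaps
  da_db <- truth$pair_stats
  up_row <- da_db[da_db$disease_i == "DA" & da_db$disease_j == "DB" &
                    da_db$direction == "up", ]
  expect_equal(up_row$n_shared, 4L)
})

test_that("simulate_ppi separates planted hubs and is deterministic", {
  hubs <- data.frame(node = c("N0001", "N0002"), min_degree = c(20L, 18L))
  sim <- simulate_ppi(60L, 120L, hubs, seed = 9L)
  deg <- ppi_degree(sim$network)
  expect_equal(unname(deg[c("N0001", "N0002")]), c(20, 18))
  expect_lt(max(deg[setdiff(names(deg), hubs$node)]), 18)
  expect_equal(top_hubs(sim$network, k = 2L)$protein, c("N0001", "N0002"))
  expect_equal(sim$truth$hubs, c("N0001", "N0002"))

  sim2 <- simulate_ppi(60L, 120L, hubs, seed = 9L)
  expect_identical(sim$network$edges, sim2$network$edges)
})

test_that("a single hub wired to every other node forms a star", {
  sim <- simulate_ppi(8L, 7L, data.frame(node = "N0003", min_degree = 7L),
                      seed = 3L)
  deg <- ppi_degree(sim$network)
  expect_equal(unname(deg["N0003"]), 7)
  expect_true(all(deg[setdiff(names(deg), "N0003")] == 1))
})

test_that("infeasible hub requests are rejected up front", {
  expect_error(simulate_ppi(10L, 3L,
                            data.frame(node = "N0001", min_degree = 8L)),
               "budget")
  expect_error(simulate_ppi(10L, 50L,
                            data.frame(node = "N0001", min_degree = 12L)),
               "infeasible")
  expect_error(simulate_ppi(10L, 50L,
                            data.frame(node = "N0001", min_degree = 1L)),
               "at least 2")
})

test_that("simulate_gmt plants the requested overlap deterministically", {
  universe <- sprintf("G%05d", 1:300)
  query <- universe[1:20]
  sim <- simulate_gmt(40L, c(10L, 30L), universe,
                      planted_overlap_fraction = 0.8, query = query,
                      seed = 21L)
  planted <- sim$library$terms[[sim$truth$planted_term]]
  expect_equal(sim$truth$planted_overlap, 16L)
  expect_equal(length(intersect(planted, toupper(query))), 16L)

  full <- simulate_gmt(10L, c(5L, 25L), universe, 1.0, query, seed = 22L)
  expect_true(all(toupper(query) %in%
                    full$library$terms[[full$truth$planted_term]]))

  again <- simulate_gmt(40L, c(10L, 30L), universe, 0.8, query, seed = 21L)
  expect_identical(sim$library$terms, again$library$terms)

  expect_error(simulate_gmt(5L, c(10L, 500L), universe, 0.8, query),
               "universe")
})

test_that("writers emit the dialects the readers parse", {
  planted <- data.frame(gene = "G00001", disease = "DA", direction = "up")
  sim <- simulate_expression(two_disease_design(planted = planted))
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "e.tsv"); gp <- file.path(dir, "g.tsv")
  write_expression_tsv(sim$datasets$DA, mp, gp)
  back <- read_expression(mp, gp, "DA")
  expect_equal(back$values, sim$datasets$DA$values, tolerance = 1e-12)
  expect_equal(back$groups, sim$datasets$DA$groups)

  ppi <- simulate_ppi(20L, 30L, data.frame(node = "N0001", min_degree = 6L),
                      seed = 2L)
  ep <- file.path(dir, "edges.tsv")
  write_edge_list(ppi$network, ep)
  back_net <- read_edge_list(ep)
  expect_equal(back_net$edges, ppi$network$edges)

  gmt <- simulate_gmt(5L, c(3L, 6L), sprintf("G%03d", 1:50), 1,
                      sprintf("G%03d", 1:3), seed = 4L)
  lp <- file.path(dir, "lib.gmt")
  write_gmt(gmt$library, lp)
  expect_equal(read_gmt(lp)$terms, gmt$library$terms)
})
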
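cfg4 <- run_config()

test_that("ranks follow attack order with unattacked prey on top", {
  pop <- founder_population(cfg4, seed = 1)
  grouping <- camosim:::default_grouping(pop, cfg4)
  ids <- grouping$prey_id[grouping$group == 1]
  # attacks in order b, a, d; c unattacked
  attacks <- data.frame(prey_id = ids[c(2, 1, 4)], attack_index = 1:3)
  # fill the other groups completely so the table is whole
  rest <- do.call(rbind, lapply(2:6, function(g) {
    data.frame(prey_id = grouping$prey_id[grouping$group == g],
               attack_index = 1:4)
  }))
  rk <- ranks_from_attacks(rbind(attacks, rest), grouping, cfg4, seed = 2)
  g1 <- rk[rk$group == 1, ]
  expect_equal(g1$fitness_rank[match(ids[c(2, 1, 4)], g1$prey_id)], 1:3)
  expect_equal(g1$fitness_rank[match(ids[3], g1$prey_id)], 4L)
  # fully attacked groups rank in slot order
  g2 <- rk[rk$group == 2, ]
  expect_equal(g2$fitness_rank, 1:4)
})

test_that("unattacked ties are a seeded permutation of the top ranks", {
  pop <- founder_population(cfg4, seed = 1)
  grouping <- camosim:::default_grouping(pop, cfg4)
  attacks <- do.call(rbind, lapply(1:6, function(g) {
    data.frame(prey_id = grouping$prey_id[grouping$group == g][1:2],
               attack_index = 1:2)
  }))
  seen <- replicate(40, {
    rk <- ranks_from_attacks(attacks, grouping, cfg4,
                             seed = sample.int(1e6, 1))
    g1 <- rk[rk$group == 1, ]
    expect_setequal(g1$fitness_rank, 1:4)
    g1$fitness_rank[3] # first unattacked prey's rank
  })
  expect_setequal(unique(seen), c(3L, 4L)) # both assignments occur
  expect_identical(ranks_from_attacks(attacks, grouping, cfg4, seed = 5),
                   ranks_from_attacks(attacks, grouping, cfg4, seed = 5))
})

test_that("invalid attack records raise descriptive errors", {
  pop <- founder_population(cfg4, seed = 1)
  grouping <- camosim:::default_grouping(pop, cfg4)
  expect_error(ranks_from_attacks(
    data.frame(prey_id = "nope", attack_index = 1), grouping, cfg4),
    "unknown prey")
  dup <- data.frame(prey_id = rep(grouping$prey_id[1], 2),
                    attack_index = 1:2)
  expect_error(ranks_from_attacks(dup, grouping, cfg4), "duplicate attack")
})

test_that("survivors are ranks 3 and 4 per group, plus quoted-rule rescues", {
  rk_now <- random_rank_table(cfg4, seed = 10)
  sel <- select_survivors(rk_now, NULL, cfg4)
  expect_length(sel$survivors, 12)
  expect_length(sel$rescues, 0)
  expect_setequal(sel$survivors,
                  rk_now$prey_id[rk_now$fitness_rank >= 3])

  # rescue: rank 4 in N-1, rank 1 in N -> rescued
  rk_prev <- rk_now
  pid <- rk_now$prey_id[rk_now$fitness_rank == 1][1]
  rk_prev$fitness_rank[rk_prev$prey_id == pid] <- 4L
  other <- rk_prev$prey_id[rk_prev$group == rk_prev$group[rk_prev$prey_id == pid] &
                             rk_prev$fitness_rank == 4 &
                             rk_prev$prey_id != pid]
  rk_prev$fitness_rank[rk_prev$prey_id %in% other] <-
    rk_now$fitness_rank[rk_now$prey_id == pid]
  sel2 <- select_survivors(rk_now, rk_prev, cfg4)
  expect_true(pid %in% sel2$rescues)
  expect_true(pid %in% sel2$survivors)

  # previous rank 3 does not rescue
  rk_prev3 <- rk_now
  rk_prev3$fitness_rank[rk_prev3$prey_id == pid] <- 3L
  sel3 <- select_survivors(rk_now, rk_prev3, cfg4)
  expect_false(pid %in% sel3$rescues)

  expect_error(select_survivors(rk_now, random_rank_table(
    cfg4, seed = 3, ids = sprintf("zz%02d", 1:24)), cfg4),
    "different populations")
})

test_that("GA rule suite holds over 1000 randomised rank histories", {
  # property: survivors == {ranks 3,4 per group} union rescues; rescues
  # exactly match (previous rank == group size AND current rank in {1,2})
  set.seed(99)
  for (i in 1:1000) {
    ids <- sprintf("p%02d", 1:24)
    cur <- random_rank_table(cfg4, seed = i, ids = ids)
    prev <- random_rank_table(cfg4, seed = i + 5e5, ids = ids)
    sel <- select_survivors(cur, prev, cfg4)
    base <- cur$prey_id[cur$fitness_rank >= 3]
    prev_rank <- prev$fitness_rank[match(cur$prey_id, prev$prey_id)]
    want_rescue <- cur$prey_id[cur$fitness_rank %in% c(1, 2) &
                                 prev_rank == 4]
    expect_setequal(sel$rescues, want_rescue)
    expect_setequal(sel$survivors, union(base, want_rescue))
    expect_true(length(sel$survivors) >= 12 &&
                  length(sel$survivors) <= 24)
  }
})

test_that("breeding produces a full, lineage-tracked offspring population", {
  pop <- founder_population(cfg4, seed = 3)
  surv <- pop$genomes[1:12]
  nxt <- breed_next_generation(surv, cfg4, seed = 4, generation = 1)
  expect_length(nxt$genomes, 24)
  surv_ids <- vapply(surv, function(g) g$id, character(1))
  for (g in nxt$genomes) {
    expect_true(all(g$parent_ids %in% surv_ids))
    expect_length(g$parent_ids, 2)
  }
  expect_error(breed_next_generation(surv[1], cfg4, seed = 1,
                                     generation = 1), "at least 2")

  # mutation rate 0, two identical parents -> clones
  cfg0 <- run_config(mutation_rate = 0)
  twin <- list(surv[[1]], camo_genome(surv[[1]]$genes, id = "twin"))
  out <- breed_next_generation(twin, cfg0, seed = 6, generation = 1)
  for (g in out$genomes) expect_equal(g$genes, surv[[1]]$genes)
})

test_that("random-control selection is rank-blind and group-balanced", {
  pop <- founder_population(cfg4, seed = 8)
  grouping <- camosim:::default_grouping(pop, cfg4)
  surv <- random_control_selection(grouping, cfg4, seed = 1)
  expect_length(surv, 12)
  for (g in 1:6) {
    expect_length(intersect(surv, grouping$prey_id[grouping$group == g]), 2)
  }
  # hypergeometric oracle: each prey survives with probability 1/2
  counts <- setNames(rep(0, 24), grouping$prey_id)
  n_rep <- 10000
  for (s in 1:n_rep) {
    sv <- random_control_selection(grouping, cfg4, seed = s)
    counts[sv] <- counts[sv] + 1
  }
  expect_true(all(abs(counts / n_rep - 0.5) < 0.02))
})

test_that("advance_generation conserves size and persists survivors", {
  pop <- founder_population(cfg4, seed = 5)
  rk <- random_rank_table(cfg4, seed = 6, ids = population_ids(pop))
  rec <- generation_record(pop, ranks = rk, seed = 1)
  nxt <- advance_generation(rec, NULL, cfg4, seed = 7)
  expect_length(nxt$population$genomes, 24)
  expect_equal(nxt$population$generation, 1L)
  scored <- attr(nxt, "scored")
  expect_length(scored$survivors, 12)
  # survivors carried over unchanged, offspring bred from them
  ids_next <- population_ids(nxt$population)
  expect_setequal(intersect(ids_next, population_ids(pop)),
                  scored$survivors)
  expect_error(advance_generation(generation_record(pop), NULL, cfg4,
                                  seed = 1), "no ranks")
  # determinism
  nxt2 <- advance_generation(rec, NULL, cfg4, seed = 7)
  expect_identical(genomes_to_df(nxt$population$genomes),
                   genomes_to_df(nxt2$population$genomes))
})

test_that("chaining scored generations plus a final one counts correctly", {
  # 10 scored generations (0-9) then the extra unscored generation: 11
  # populations exist, indices 0-10
  cfg <- run_config(n_generations = 10L, seed = 2)
  pop <- founder_population(cfg)
  recs <- list()
  prev <- NULL
  rec <- NULL
  for (g in 0:9) {
    rk <- random_rank_table(cfg, seed = 100 + g, ids = population_ids(pop))
    cur <- generation_record(pop, ranks = rk, seed = g)
    nxt <- advance_generation(cur, prev, cfg, seed = 200 + g)
    prev <- attr(nxt, "scored")
    recs[[g + 1]] <- prev
    pop <- nxt$population
  }
  recs[[11]] <- generation_record(pop)
  expect_length(recs, 11)
  expect_equal(recs[[11]]$population$generation, 10L)
  sizes <- vapply(recs, function(r) length(r$population$genomes),
                  numeric(1))
  expect_true(all(sizes == 24))
})
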
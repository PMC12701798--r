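test_that("cell sampling is multinomial in the final clone sizes", {
  set.seed(10)
  lay <- tiny_layout()
  cfg <- quick_engine(lay, K = 600, n_min = 300, initial_cells = 5)
  rec <- run_forward(cfg, seed = 2)
  # single surviving clone: everything assigned to it
  if (rec$n_clones == 1L) {
    sm <- sample_observed_cells(rec, 20)
    expect_true(all(sm$clone_id == 1L))
  }
  # synthetic two-clone record: 90% / 10%
  rec2 <- rec
  rec2$counts <- matrix(c(900L, 100L), 2, 1)
  rec2$clones <- list(rec$clones[[1]],
                      list(id = 2L, parent = 1L, birth_gen = 1L,
                           birth_site = 1L, genome = rec$clones[[1]]$genome))
  rec2$n_clones <- 2L
  sm <- sample_observed_cells(rec2, 1000)
  frac <- mean(sm$clone_id == 1L)
  expect_lt(abs(frac - 0.9), 3 * sqrt(0.9 * 0.1 / 1000))
  expect_identical(nrow(sample_observed_cells(rec, 0)), 0L)
  expect_error(sample_observed_cells(rec, 1e7), "site 1")
})

test_that("clone tree contraction preserves driver histories", {
  set.seed(33)
  lay <- small_layout()
  cfg <- quick_engine(lay, K = 2000, n_min = 1000,
                      rates = driver_rates(2e-3, 2e-3, 1e-3, 1e-3, 1e-4))
  rec <- run_forward(cfg, seed = 8)
  sm <- sample_observed_cells(rec, 60)
  ct <- build_clone_tree(sm, rec)
  expect_true(ct$root %in% ct$nodes)
  expect_identical(sum(ct$weights), 60L)
  # every node's edge events equal the founding events of the registry
  # clones skipped between it and its tree parent, in birth order
  for (cid in ct$nodes) {
    evs <- ct$edge_events[[as.character(cid)]]
    chain <- integer(0)
    p <- cid
    stopat <- ct$parent[[as.character(cid)]]
    while (!is.na(p) && !identical(p, stopat)) {
      chain <- c(p, chain)
      p <- rec$clones[[p]]$parent
      if (!is.na(stopat) && is.na(p)) break
    }
    expected <- Filter(Negate(is.null),
                       lapply(chain, function(c) rec$clones[[c]]$event))
    expect_identical(evs, expected)
    # edge length = birth generation difference
    if (!is.na(stopat))
      expect_gte(ct$birth_gen[[as.character(cid)]],
                 ct$birth_gen[[as.character(stopat)]])
  }
  # a sample hitting a single clone contracts to a single-node tree
  one <- sm[sm$clone_id == sm$clone_id[1], , drop = FALSE]
  ct1 <- build_clone_tree(one, rec)
  expect_length(ct1$nodes, 1L)
  expect_identical(ct1$root, one$clone_id[1])
})

test_that("the within-clone coalescent has the right marginal behaviour", {
  # one entering lineage passes through untouched
  leaf <- oncosim:::.new_lineage_node(time = 50, label = "cell_1_1")
  out <- resolve_within_clone(list(list(node = leaf, entry_gen = 50)),
                              sizes = rep(10, 51), birth_gen = 0)
  expect_identical(out$label, "cell_1_1")
  # lineages entering at the birth generation merge there immediately
  set.seed(2)
  entering <- lapply(1:5, function(i)
    list(node = oncosim:::.new_lineage_node(time = 10,
                                            label = paste0("c", i)),
         entry_gen = 10))
  out <- resolve_within_clone(entering, sizes = rep(1000, 11), birth_gen = 10)
  times <- c()
  walk <- function(n) {
    if (length(n$children)) {
      times <<- c(times, n$time)
      for (ch in n$children) walk(ch)
    }
  }
  walk(out)
  expect_true(all(times == 10))
  # constant N, two lineages: mean pairwise coalescence time ~ N
  set.seed(91)
  N <- 200
  t_final <- 6000
  sizes <- rep(N, t_final + 1)
  tcoal <- replicate(400, {
    ent <- lapply(1:2, function(i)
      list(node = oncosim:::.new_lineage_node(time = t_final,
                                              label = paste0("c", i)),
           entry_gen = t_final))
    out <- resolve_within_clone(ent, sizes, birth_gen = 0)
    t_final - out$time
  })
  expect_lt(abs(mean(tcoal) - N) / N, 0.15)
})

test_that("the assembled lineage tree is leaf-conserving, binary and time-consistent", {
  set.seed(14)
  lay <- small_layout()
  cfg <- quick_engine(lay, K = 2000, n_min = 1000, n_sites = 2,
                      p_base = 5e-4,
                      rates = driver_rates(2e-3, 2e-3, 1e-3, 1e-3, 1e-4),
                      initial_cells = 10)
  rec <- run_forward(cfg, seed = 4)
  sm <- sample_observed_cells(rec, c(40, 25))
  ct <- build_clone_tree(sm, rec)
  tree <- assemble_cell_lineage(ct, rec, sm)

  expect_identical(tree$n_leaves, 65L)
  leaves <- lineage_leaves(tree)
  expect_setequal(leaves, sm$cell_id)

  n_internal <- 0L
  check <- function(node) {
    if (!length(node$children)) {
      # ultrametric in generations: all leaves at the final generation
      expect_identical(node$time, rec$generations)
      return(invisible(NULL))
    }
    expect_length(node$children, 2L)  # fully binary
    n_internal <<- n_internal + 1L
    for (ch in node$children) {
      expect_gte(ch$time, node$time)  # time increases rootward -> leafward
      check(ch)
    }
  }
  check(tree$root)
  expect_identical(n_internal, tree$n_leaves - 1L)

  # contracting by clone identity recovers the clone tree: the leaves under
  # each clone's subtree root are exactly the cells of that clone's subtree
  clone_leafset <- function(node) {
    sets <- list()
    walk <- function(n) {
      lv <- character(0)
      if (!length(n$children)) lv <- n$label
      for (ch in n$children) lv <- c(lv, walk(ch))
      if (!is.na(n$clone_root)) sets[[as.character(n$clone_root)]] <<- lv
      lv
    }
    walk(node)
    sets
  }
  sets <- clone_leafset(tree$root)
  desc <- function(cid) {
    kids <- ct$nodes[!is.na(ct$parent) & ct$parent == cid]
    c(cid, unlist(lapply(kids, desc)))
  }
  for (cid in ct$nodes) {
    expected <- sm$cell_id[sm$clone_id %in% desc(cid)]
    expect_setequal(sets[[as.character(cid)]], expected)
  }
})

test_that("passenger annotation adds Poisson-rate events and exact replay genomes", {
  set.seed(77)
  lay <- small_layout()
  cfg <- quick_engine(lay, K = 1200, n_min = 600,
                      rates = driver_rates(1e-3, 1e-3, 5e-4, 5e-4, 5e-5),
                      initial_cells = 10)
  rec <- run_forward(cfg, seed = 6)
  sm <- sample_observed_cells(rec, 30)
  ct <- build_clone_tree(sm, rec)
  tree0 <- assemble_cell_lineage(ct, rec, sm)

  # zero passenger rate: leaf genomes equal the clone genomes
  t0 <- add_passenger_mutations(tree0, passenger_rates(0, 0))
  gen0 <- realize_leaf_genomes(t0)
  for (i in seq_len(nrow(sm))) {
    expect_identical(total_copy_number(gen0[[sm$cell_id[i]]]),
                     total_copy_number(rec$clones[[sm$clone_id[i]]]$genome))
  }

  # positive rates: total passenger count matches the Poisson expectation
  nu <- 0.05
  total_len <- 0
  sumlen <- function(node) {
    for (ch in node$children) {
      total_len <<- total_len + (ch$time - node$time)
      sumlen(ch)
    }
  }
  sumlen(tree0$root)
  t1 <- add_passenger_mutations(tree0, passenger_rates(nu * 0.9, nu * 0.1))
  n_pass <- 0L
  cnt <- function(node) {
    for (ev in node$events) {
      if (identical(ev$origin, "passenger") ||
          (ev$kind != "snv" && !is.null(ev$generation) &&
           ev$generation %% 1 != 0)) n_pass <<- n_pass + 1L
    }
    for (ch in node$children) cnt(ch)
  }
  cnt(t1$root)
  expect_lt(abs(n_pass - nu * total_len), 4 * sqrt(nu * total_len) + 3)

  # realized leaf genomes are an exact replay of the recorded edge events
  gen1 <- realize_leaf_genomes(t1)
  expect_setequal(names(gen1), sm$cell_id)
  stored <- list()
  grab <- function(node) {
    if (!length(node$children)) stored[[node$label]] <<- node$genome
    for (ch in node$children) grab(ch)
  }
  grab(t1$root)
  for (cell in names(gen1)) {
    expect_same_genome_state(gen1[[cell]], stored[[cell]])
  }

  # two leaves of the same clone share their driver events
  dup <- sm$clone_id[duplicated(sm$clone_id)]
  if (length(dup)) {
    cells <- sm$cell_id[sm$clone_id == dup[1]][1:2]
    drivers <- function(g) {
      # engine drivers carry integer generations; passenger times are
      # continuous and passenger SNVs are tagged by origin
      evs <- Filter(function(e) {
        if (e$kind == "snv") return(identical(e$origin, "driver"))
        gn <- e$generation
        is.null(gn) || is.na(gn) || gn %% 1 == 0
      }, genome_events(g))
      vapply(evs, `[[`, character(1), "kind")
    }
    expect_identical(drivers(gen1[[cells[1]]]), drivers(gen1[[cells[2]]]))
  }

  # determinism of the whole stage-2 path
  set.seed(123)
  a <- add_passenger_mutations(tree0, passenger_rates(0.01, 0.002))
  set.seed(123)
  b <- add_passenger_mutations(tree0, passenger_rates(0.01, 0.002))
  expect_identical(realize_leaf_genomes(a), realize_leaf_genomes(b))
})
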
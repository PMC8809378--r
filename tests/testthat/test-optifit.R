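# Small reference-fitting scenarios with hand-enumerable optima.

ref_wabc <- function() {
  # refs: OTU1 = {A, B} (edge A-B), C a singleton; query W near A and B
  g <- graph_from_edges(c("A", "B", "C", "W"),
                        list(c("A", "B"), c("W", "A"), c("W", "B")))
  ref <- tibble::tibble(id = c("A", "B", "C"),
                        otu = c("otu_1", "otu_1", "otu_2"))
  list(graph = g, ref = ref)
}

test_that("a query joins the reference OTU holding its neighbors", {
  fx <- ref_wabc()
  # initial state: W singleton
  init <- confusion_matrix(
    fx$graph, rbind(fx$ref, tibble::tibble(id = "W", otu = "self")))
  expect_equal(unlist(init), c(tp = 1, fp = 0, fn = 2, tn = 3))

  res <- optifit(fx$graph, fx$ref, "W", mode = "closed", seed = 1)
  expect_equal(unlist(res$counts), c(tp = 3, fp = 0, fn = 0, tn = 3))
  expect_equal(res$mcc, 1)
  expect_equal(res$fraction_mapped, 1)
  expect_equal(res$partition$otu[res$partition$id == "W"], "otu_1")

  # exhaustive assignment enumeration agrees
  bf <- brute_force_best_fit(fx$graph, fx$ref, "W")
  expect_equal(bf$mcc, 1)
  expect_equal(bf$assignment$otu, "otu_1")
})

test_that("a query with no similar sequence stays a singleton", {
  g <- graph_from_edges(c("A", "B", "Z"), list(c("A", "B")))
  ref <- tibble::tibble(id = c("A", "B"), otu = c("o1", "o1"))
  closed <- optifit(g, ref, "Z", mode = "closed", seed = 1)
  expect_equal(closed$unmapped_ids, "Z")
  expect_equal(closed$fraction_mapped, 0)
  expect_false("Z" %in% closed$partition$id)
  # retained-universe confusion: just the reference pair
  expect_equal(unlist(closed$counts), c(tp = 1, fp = 0, fn = 0, tn = 0))

  open <- optifit(g, ref, "Z", mode = "open", seed = 1)
  expect_true("Z" %in% open$partition$id)
  z_otu <- open$partition$otu[open$partition$id == "Z"]
  expect_equal(sum(open$partition$otu == z_otu), 1)
  expect_equal(open$fraction_mapped, 1)

  expect_equal(brute_force_best_fit(g, ref, "Z")$assignment$otu,
               NA_character_)
})

test_that("reference assignments are frozen through fitting", {
  for (seed in 1:8) {
    fx <- random_fit_instance(seed, n_ref = 7, n_query = 4, p = 0.4)
    for (mode in c("open", "closed")) {
      res <- optifit(fx$graph, fx$ref, fx$query_ids, mode = mode,
                     seed = seed)
      got <- res$partition[match(fx$ref$id, res$partition$id), ]
      expect_identical(got$otu, fx$ref$otu)
    }
  }
})

test_that("fit-phase MCC trace is monotone and queries map only with neighbors", {
  for (seed in 1:8) {
    fx <- random_fit_instance(seed + 40, n_ref = 8, n_query = 5, p = 0.35)
    res <- optifit(fx$graph, fx$ref, fx$query_ids, mode = "closed",
                   seed = seed)
    expect_true(all(diff(res$mcc_trace) >= -1e-12))
    # every mapped query has >= 1 neighbor inside its assigned OTU
    deg <- graph_edges(fx$graph)
    mapped <- setdiff(intersect(res$partition$id, fx$query_ids),
                      res$unmapped_ids)
    for (q in mapped) {
      otu_q <- res$partition$otu[res$partition$id == q]
      members <- setdiff(res$partition$id[res$partition$otu == otu_q], q)
      nb <- c(deg$id2[deg$id1 == q], deg$id1[deg$id2 == q])
      expect_gt(length(intersect(members, nb)), 0)
    }
    # closed mode: surviving labels are reference labels
    expect_true(all(res$partition$otu %in% fx$ref$otu))
  }
})

test_that("close_partition does plain set arithmetic", {
  p <- tibble::tibble(
    id = c("r1", "r2", "q1", "q2", "q3"),
    otu = c("ref_a", "ref_b", "ref_a", "solo1", "solo2"))
  out <- close_partition(p, c("ref_a", "ref_b"), c("q1", "q2", "q3"))
  expect_setequal(out$unmapped_ids, c("q2", "q3"))
  expect_setequal(out$partition$id, c("r1", "r2", "q1"))
  expect_true(all(out$partition$otu %in% c("ref_a", "ref_b")))

  # no queries mapped
  p2 <- tibble::tibble(id = c("r1", "q1"), otu = c("ref_a", "solo"))
  out2 <- close_partition(p2, "ref_a", "q1")
  expect_equal(out2$unmapped_ids, "q1")
  expect_equal(out2$partition$id, "r1")

  # all queries mapped
  p3 <- tibble::tibble(id = c("r1", "q1"), otu = c("ref_a", "ref_a"))
  out3 <- close_partition(p3, "ref_a", "q1")
  expect_equal(out3$unmapped_ids, character())
  expect_setequal(out3$partition$id, c("r1", "q1"))

  # randomized: retained universe = refs + mapped
  for (seed in 1:6) {
    fx <- random_fit_instance(seed + 70, n_ref = 6, n_query = 4)
    res <- optifit(fx$graph, fx$ref, fx$query_ids, mode = "open",
                   seed = seed)
    cl <- close_partition(res$partition, unique(fx$ref$otu), fx$query_ids)
    mapped <- setdiff(fx$query_ids, cl$unmapped_ids)
    expect_setequal(cl$partition$id, c(fx$ref$id, mapped))
  }
})

test_that("open_extend clusters leftovers de novo under fresh labels", {
  # a similar query pair plus an unrelated third: the pair must merge
  # (strictly better MCC on the leftover subgraph), the loner must not
  g <- graph_from_edges(c("A", "B", "u", "v", "w"),
                        list(c("A", "B"), c("u", "v")))
  p <- tibble::tibble(id = c("A", "B", "u", "v", "w"),
                      otu = c("r1", "r1", "s1", "s2", "s3"))
  # zero unassigned: unchanged
  expect_identical(open_extend(g, p, character()), p)

  for (seed in 1:5) {
    out <- open_extend(g, p, c("u", "v", "w"), seed = seed)
    expect_equal(out$otu[out$id == "u"], out$otu[out$id == "v"])
    expect_false(out$otu[out$id == "w"] == out$otu[out$id == "u"])
    expect_false(out$otu[out$id == "u"] %in% c("r1", "s1", "s2", "s3"))
    expect_identical(out$otu[match(c("A", "B"), out$id)], c("r1", "r1"))
  }

  expect_error(open_extend(g, p, "A"), "singleton")
})

test_that("de novo extension of two planted cliques lifts open above closed", {
  # refs form one clique; queries form two cliques unrelated to the refs
  ids <- c(paste0("r", 1:3), paste0("u", 1:3), paste0("v", 1:3))
  cl <- function(x) utils::combn(x, 2, simplify = FALSE)
  g <- graph_from_edges(ids, c(cl(paste0("r", 1:3)),
                               cl(paste0("u", 1:3)),
                               cl(paste0("v", 1:3))))
  ref <- tibble::tibble(id = paste0("r", 1:3), otu = "ref_1")
  queries <- ids[-(1:3)]
  open <- optifit(g, ref, queries, mode = "open", seed = 2)
  closed <- optifit(g, ref, queries, mode = "closed", seed = 2)
  # evaluate both over the full universe: closed leaves queries unclustered
  closed_full <- rbind(
    closed$partition,
    tibble::tibble(id = closed$unmapped_ids,
                   otu = paste0("left_", seq_along(closed$unmapped_ids))))
  expect_gte(open$mcc, mcc(confusion_matrix(g, closed_full)))
  expect_equal(open$mcc, 1)  # planted cliques are recoverable exactly
})

test_that("fitting zero queries returns the reference scoring", {
  g <- graph_from_edges(c("A", "B", "C"), list(c("A", "B")))
  ref <- tibble::tibble(id = c("A", "B", "C"),
                        otu = c("o1", "o1", "o2"))
  res <- optifit(g, ref, character(), mode = "closed", seed = 1)
  expect_true(res$no_queries)
  expect_equal(res$fraction_mapped, 1)
  expect_equal(res$partition$otu, ref$otu)
  expect_equal(res$counts, confusion_matrix(g, ref))
})

test_that("input contracts are enforced", {
  fx <- ref_wabc()
  expect_error(optifit(fx$graph, fx$ref, "nope", mode = "open"),
               "missing from the graph")
  expect_error(optifit(fx$graph, fx$ref, c("W", "A"), mode = "open"),
               "both reference and query")
  g_small <- graph_from_edges(c("A", "B"), list(c("A", "B")))
  expect_error(
    optifit(g_small, fx$ref, "W", mode = "open"),
    "universe")
})

test_that("three of four queries map in the worked fit scenario", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "fx")
  otufit_cli(c("simulate", "--preset", "fit-scenario", "--seed", "1",
               "--out-prefix", prefix, "--quiet"))
  g <- sim_graph(read_dist_columns(paste0(prefix, ".dist")),
                 ids = read_name_list(paste0(prefix, ".names")),
                 threshold = 0.03)
  ref <- read_otu_list(paste0(prefix, ".ref.list"))
  queries <- read_name_list(paste0(prefix, ".query.names"))
  for (seed in c(1, 7, 23)) {
    res <- optifit(g, ref, queries, mode = "closed", seed = seed)
    expect_equal(res$fraction_mapped, 0.75)
    expect_equal(res$unmapped_ids, "q4")
  }
})
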
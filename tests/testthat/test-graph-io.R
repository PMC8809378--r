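test_that("read_fasta takes ids from the first header token, in file order", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGA"), fa)
  expect_equal(read_fasta(fa)$id, c("a", "b"))

  writeLines(c(">a some description here", "AC"), fa)
  out <- read_fasta(fa)
  expect_equal(out$id, "a")
  expect_equal(out$sequence, "AC")

  writeLines(c(">a", "AC", ">a", "AG"), fa)
  expect_error(read_fasta(fa), "duplicate.*a")

  writeLines(character(), fa)
  expect_error(read_fasta(fa), "no records|cannot")
})

test_that("column distances threshold into edges, absent pairs stay non-edges", {
  f <- withr::local_tempfile()
  writeLines(c("a\tb\t0.02", "a\tc\t0.05"), f)
  g <- sim_graph(read_dist_columns(f), ids = c("a", "b", "c", "d"),
                 threshold = 0.03)
  ed <- graph_edges(g)
  expect_equal(nrow(ed), 1)
  expect_setequal(c(ed$id1, ed$id2), c("a", "b"))
  # absent pairs are negatives: 6 possible pairs, 1 edge
  expect_equal(total_pairs(g), 6)

  # boundary distance == threshold counts as within
  writeLines("a b 0.03", f)
  g2 <- sim_graph(read_dist_columns(f), ids = c("a", "b"), threshold = 0.03)
  expect_equal(nrow(graph_edges(g2)), 1)

  # empty stream, universe of 4
  writeLines(character(), f)
  g3 <- sim_graph(read_dist_columns(f), ids = letters[1:4], threshold = 0.03)
  expect_equal(nrow(graph_edges(g3)), 0)
  expect_equal(total_pairs(g3), 6)
})

test_that("column parsing errors and edge cases are reported precisely", {
  f <- withr::local_tempfile()
  writeLines(c("a b 0.01", "oops"), f)
  expect_error(read_dist_columns(f), "line 2")
  writeLines("a b zero", f)
  expect_error(read_dist_columns(f), "not a number")

  writeLines("a b 0.01", f)
  expect_error(sim_graph(read_dist_columns(f), ids = c("a", "x")),
               "not in the universe")

  # self-pair within threshold: ignored with a warning
  writeLines(c("a a 0.0", "a b 0.01"), f)
  expect_warning(
    g <- sim_graph(read_dist_columns(f), ids = c("a", "b")),
    "self-pair")
  expect_equal(nrow(graph_edges(g)), 1)

  # duplicate listings: consistent ones collapse, straddling ones error
  writeLines(c("a b 0.01", "b a 0.02"), f)
  g2 <- sim_graph(read_dist_columns(f), ids = c("a", "b"), threshold = 0.03)
  expect_equal(nrow(graph_edges(g2)), 1)
  writeLines(c("a b 0.01", "b a 0.05"), f)
  expect_error(sim_graph(read_dist_columns(f), ids = c("a", "b")),
               "both sides of threshold")

  # universe is required with sparse column input
  expect_error(sim_graph(tibble::tibble(id1 = "a", id2 = "b",
                                        distance = 0.01)),
               "universe")
})

test_that("matrix distances parse in both dialects and match column input", {
  f <- withr::local_tempfile()
  writeLines(c("3", "a", "b 0.01", "c 0.10 0.02"), f)
  d <- read_dist_matrix(f)
  g <- sim_graph(d, threshold = 0.03)
  sig <- graph_edges(g)
  expect_equal(nrow(sig), 2)
  expect_setequal(paste(sig$id1, sig$id2),
                  c("a b", "b c"))

  # n = 1: no pairs
  writeLines(c("1", "solo"), f)
  g1 <- sim_graph(read_dist_matrix(f), threshold = 0.03)
  expect_equal(length(g1$ids), 1)
  expect_equal(nrow(graph_edges(g1)), 0)

  # row count mismatch
  writeLines(c("3", "a", "b 0.01"), f)
  expect_error(read_dist_matrix(f), "declared 3")

  # square dialect, symmetric
  writeLines(c("3",
               "a 0.00 0.01 0.10",
               "b 0.01 0.00 0.02",
               "c 0.10 0.02 0.00"), f)
  gsq <- sim_graph(read_dist_matrix(f), threshold = 0.03)
  expect_equal(edge_signature(gsq), edge_signature(g))

  # square dialect, asymmetric beyond 1e-9
  writeLines(c("2", "a 0.00 0.01", "b 0.02 0.00"), f)
  expect_error(read_dist_matrix(f), "not symmetric")
})

test_that("equivalent column and matrix inputs build identical graphs", {
  withr::with_seed(42, {
    n <- 8
    ids <- paste0("s", 1:n)
    dmat <- matrix(0, n, n)
    dmat[upper.tri(dmat)] <- round(stats::runif(n * (n - 1) / 2, 0, 0.08), 4)
    dmat <- dmat + t(dmat)
    fcol <- withr::local_tempfile()
    fmat <- withr::local_tempfile()
    pr <- which(upper.tri(dmat), arr.ind = TRUE)
    writeLines(sprintf("%s %s %s", ids[pr[, 1]], ids[pr[, 2]],
                       dmat[pr]), fcol)
    writeLines(c(as.character(n),
                 vapply(seq_len(n), function(i) {
                   paste(c(ids[i], format(dmat[i, seq_len(i - 1)],
                                          scientific = FALSE)),
                         collapse = " ")
                 }, character(1))), fmat)
    g_col <- sim_graph(read_dist_columns(fcol), ids = ids, threshold = 0.03)
    g_mat <- sim_graph(read_dist_matrix(fmat), threshold = 0.03)
    expect_equal(edge_signature(g_col), edge_signature(g_mat))

    # permuting the column file's lines changes nothing
    lines <- readLines(fcol)
    writeLines(sample(lines), fcol)
    g_perm <- sim_graph(read_dist_columns(fcol), ids = ids, threshold = 0.03)
    expect_identical(g_perm$edges, g_col$edges)
  })
})

test_that("total_pairs counts unordered pairs", {
  expect_equal(total_pairs(54), 1431)
  expect_equal(total_pairs(1), 0)
  expect_equal(total_pairs(4), 6)
  expect_equal(total_pairs(0), 0)
  expect_error(total_pairs(-1))
})
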
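single_entry_cube <- function(value = 0.7, t = 1, j = 5, q = 2) {
  a <- array(0, dim = c(3, 8, 2),
             dimnames = list(paste0("L", 1:3), paste0("F", 1:8),
                             paste0("Q", 1:2)))
  a[t, j, q] <- value
  coefficient_cube(a)
}

test_that("an all-zero cube yields a valid empty graph with a warning", {
  zero <- coefficient_cube(array(0, c(2, 3, 2),
                                 dimnames = list(c("a", "b"),
                                                 c("x", "y", "z"),
                                                 c("u", "v"))))
  expect_warning(g <- build_sankey_graph(zero, 0),
                 class = "csea_empty_graph_warning")
  expect_equal(nrow(g$nodes), 0)
  expect_equal(nrow(g$links), 0)
})

test_that("a single nonzero entry makes 3 nodes and 2 links of its magnitude", {
  g <- build_sankey_graph(single_entry_cube(0.7))
  expect_equal(nrow(g$nodes), 3)
  expect_equal(nrow(g$links), 2)
  expect_equal(g$links$weight, c(0.7, 0.7))
  expect_setequal(g$nodes$layer, c("level", "feature", "task"))
  expect_setequal(g$links$source, c("level:L1", "feature:F5"))
  expect_setequal(g$links$target, c("feature:F5", "task:Q2"))

  neg <- build_sankey_graph(single_entry_cube(-1.2))
  expect_equal(neg$links$weight, c(1.2, 1.2))
  expect_equal(neg$links$sign, c(-1, -1))
})

test_that("per-feature flow is conserved and equals the surviving magnitude sum", {
  set.seed(77)
  for (rep in 1:10) {
    cube <- make_sparse_cube(3, 56, 2, density = 0.1, seed = 700 + rep)
    g <- build_sankey_graph(cube, 0)
    feats <- g$nodes$id[g$nodes$layer == "feature"]
    for (f in feats) {
      inw <- sum(g$links$weight[g$links$target == f])
      outw <- sum(g$links$weight[g$links$source == f])
      label <- sub("^feature:", "", f)
      expect_equal(inw, outw, tolerance = 1e-12)
      expect_equal(inw, sum(abs(cube[, label, ])), tolerance = 1e-12)
    }
    expect_equal(sum(g$links$weight), 2 * sum(abs(cube)), tolerance = 1e-12)
  }
})

test_that("raising the threshold never adds nodes or links", {
  cube <- make_sparse_cube(3, 30, 2, density = 0.5, seed = 81)
  ths <- c(0, 0.2, 0.5, 1, 2)
  prev <- build_sankey_graph(cube, 0)
  for (th in ths[-1]) {
    g <- suppressWarnings(build_sankey_graph(cube, th))
    expect_true(all(g$nodes$id %in% prev$nodes$id))
    expect_true(all(paste(g$links$source, g$links$target) %in%
                      paste(prev$links$source, prev$links$target)))
    prev <- g
  }
})

test_that("the intersection-pattern count matches exhaustive enumeration", {
  expect_equal(count_intersection_patterns(1, 1), 1)
  expect_equal(count_intersection_patterns(2, 3), 21)
  for (m in 1:5) for (Tl in 1:5) {
    # enumerate every (task-subset, level-subset) pair and count nonempty ones
    tsub <- expand.grid(rep(list(c(FALSE, TRUE)), m))
    lsub <- expand.grid(rep(list(c(FALSE, TRUE)), Tl))
    n <- 0L
    for (i in seq_len(nrow(tsub))) for (j in seq_len(nrow(lsub)))
      if (any(unlist(tsub[i, ])) && any(unlist(lsub[j, ]))) n <- n + 1L
    expect_equal(count_intersection_patterns(m, Tl), n)
  }
  expect_error(count_intersection_patterns(0, 2),
               class = "csea_contract_error")
})

test_that("feature patterns partition selected features within the bound", {
  cube <- single_entry_cube()
  expect_equal(assign_intersection_pattern(cube, "F5"),
               list(tasks = "Q2", levels = "L1"))
  expect_equal(assign_intersection_pattern(cube, "F1"),
               list(tasks = character(), levels = character()))
  expect_error(assign_intersection_pattern(cube, "nope"),
               class = "csea_lookup_error")

  set.seed(91)
  rc <- make_sparse_cube(3, 40, 3, density = 0.2, seed = 91)
  pats <- vapply(dimnames(rc)[[2]], function(f) {
    p <- assign_intersection_pattern(rc, f)
    paste(paste(p$tasks, collapse = ","), paste(p$levels, collapse = ","),
          sep = "|")
  }, "")
  selected <- pats[pats != "|"]
  expect_lte(length(unique(selected)), count_intersection_patterns(3, 3))
})

test_that("sankey graphs survive the JSON sidecar round-trip", {
  g <- build_sankey_graph(make_sparse_cube(3, 20, 2, density = 0.3,
                                           seed = 55))
  path <- withr::local_tempfile(fileext = ".json")
  write_sankey_json(g, path)
  back <- read_sankey_json(path)
  expect_identical(back$nodes, g$nodes)
  expect_identical(back$links, g$links)

  e <- empty_graph <- suppressWarnings(
    build_sankey_graph(single_entry_cube(0), 0))
  epath <- withr::local_tempfile(fileext = ".json")
  write_sankey_json(e, epath)
  eb <- read_sankey_json(epath)
  expect_equal(nrow(eb$nodes), 0)
  expect_equal(nrow(eb$links), 0)
})

test_that("render_sankey writes self-contained HTML plus a faithful sidecar", {
  dir <- withr::local_tempdir()
  cube <- make_sparse_cube(3, 56, 2, density = 0.15, seed = 42)
  g <- build_sankey_graph(cube)
  paths <- render_sankey(g, file.path(dir, "diagram.html"))
  expect_true(file.exists(paths$html))
  expect_true(file.exists(paths$json))
  html <- paste(readLines(paths$html), collapse = "\n")
  for (lbl in g$nodes$label) expect_match(html, lbl, fixed = TRUE)
  expect_identical(read_sankey_json(paths$json)$links, g$links)

  empty <- suppressWarnings(build_sankey_graph(single_entry_cube(0), 0))
  ep <- render_sankey(empty, file.path(dir, "empty.html"))
  ehtml <- paste(readLines(ep$html), collapse = "\n")
  expect_match(ehtml, "Empty diagram", fixed = TRUE)
})
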
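make_outcome <- function(collection, lists, min_size = 1L, ...) {
  merged <- merge_rankings(lists)
  sized <- remove_undersized(merged, collection, min_size)
  filter_redundant(sized$merged, collection, filter_config(min_size, ...),
                   undersized_ids = sized$undersized_ids,
                   unannotated_ids = sized$unannotated_ids)
}

test_that("group rank per source is the best rank over group members", {
  col <- micro_collection()
  # A leads source S1 and represents C; in S2 the represented term C sits at
  # rank 1, ahead of A at rank 2, so the group's S2 rank is 1 via C
  l1 <- ranked_term_list("A", "S1")
  l2 <- ranked_term_list(c("C", "A"), "S2")
  out <- make_outcome(col, list(l1, l2))
  expect_identical(representatives(out), "A")
  expect_identical(out$groups[[1]]$represented_ids, "C")
  r <- group_source_ranks(out, list(l1, l2))
  expect_equal(r["A", "S2"], 1L)
  expect_equal(r["A", "S1"], 1L)

  # single source, A first so that A represents C: group rank 1 via A
  lst2 <- ranked_term_list(c("A", "C", "D"), "S")
  out2 <- make_outcome(col, list(lst2))
  r2 <- group_source_ranks(out2, list(lst2))
  expect_identical(representatives(out2), c("A", "D"))
  expect_equal(r2["A", "S"], 1L)
  expect_equal(r2["D", "S"], 3L)
})

test_that("groups absent from a source get NA, single members their rank", {
  col <- micro_collection()
  l1 <- ranked_term_list(c("B", "D"), "u")
  l2 <- ranked_term_list(c("x1", "x2", "B"), "v")
  col2 <- annotation_collection(c(col$gene_sets,
                                  list(x1 = c("g7", "g8"), x2 = c("g9", "g10"))))
  out <- make_outcome(col2, list(l1, l2))
  r <- group_source_ranks(out, list(l1, l2))
  expect_equal(r["D", "u"], 2L)
  expect_true(is.na(r["D", "v"]))
  expect_equal(r["B", "v"], 3L)
})

test_that("group_source_ranks rejects alias mismatches", {
  col <- micro_collection()
  lst <- ranked_term_list(c("A", "B"), "S")
  out <- make_outcome(col, list(lst))
  expect_error(group_source_ranks(out, list(ranked_term_list(c("A", "B"), "T"))),
               "aliases")
})

test_that("quartile assignment follows ceiling(4r/L) with clipping", {
  col <- micro_collection()
  lst <- ranked_term_list(c("B", "C", "A", "D"), "S")  # no coverage of B,C by later A
  out <- make_outcome(col, list(lst))
  r <- group_source_ranks(out, list(lst))
  q <- assign_quartiles(r, list(lst))
  expect_equal(q["B", "S"], 1L)  # rank 1 of 4
  expect_equal(q["C", "S"], 2L)  # rank 2 of 4
  expect_equal(q["D", "S"], 4L)  # rank 4 of 4
  # degenerate single-term list: rank 1 of 1 -> ceiling(4) = Q4 by policy
  one <- ranked_term_list("D", "solo")
  col_d <- annotation_collection(list(D = c("g5", "g6")))
  out1 <- make_outcome(col_d, list(one))
  q1 <- assign_quartiles(group_source_ranks(out1, list(one)), list(one))
  expect_equal(q1["D", "solo"], 4L)
})

test_that("quartile is monotone non-decreasing in rank for fixed length", {
  for (L in c(1L, 3L, 4L, 7L, 50L)) {
    q <- vapply(seq_len(L), function(r) min(4, max(1, ceiling(4 * r / L))),
                numeric(1))
    lst <- ranked_term_list(sprintf("t%02d", seq_len(L)), "s")
    m <- matrix(seq_len(L), ncol = 1, dimnames = list(lst$term_ids, "s"))
    got <- assign_quartiles(m, list(lst))
    expect_equal(as.vector(got), as.integer(q))
    expect_true(all(diff(got[, 1]) >= 0))
  }
})

test_that("reports for the worked micro-example have 3 and 4 rows", {
  col <- micro_collection()
  lst <- ranked_term_list(c("B", "A", "C", "D"), "S")
  out <- make_outcome(col, list(lst))
  r <- group_source_ranks(out, list(lst))
  dir <- tempfile()
  paths <- write_reports(out, r, col, dir, "micro")
  summary <- read.delim(paths[["summary"]])
  detailed <- read.delim(paths[["detailed"]])
  expect_equal(nrow(summary), 3L)
  expect_equal(nrow(detailed), 4L)
  expect_identical(summary$representative_id, c("B", "A", "D"))
  expect_equal(summary$n_represented, c(0L, 1L, 0L))
  expect_equal(summary$term_size, c(2L, 4L, 2L))
  expect_identical(detailed$role,
                   c("representative", "representative", "represented",
                     "representative"))
  html <- readLines(paths[["html"]])
  expect_true(any(grepl("broad term", html)))
})

test_that("empty outcomes give header-only tables and an empty HTML list", {
  col <- annotation_collection(list(A = sprintf("g%d", 1:3)))
  m <- merge_rankings(list(ranked_term_list("A", "S")))
  sized <- remove_undersized(m, col, 10L)  # A is undersized -> nothing left
  out <- filter_redundant(sized$merged, col, filter_config(10L),
                          undersized_ids = sized$undersized_ids)
  r <- group_source_ranks(out, list(ranked_term_list("A", "S")))
  dir <- tempfile()
  paths <- write_reports(out, r, col, dir, "empty")
  expect_equal(nrow(read.delim(paths[["summary"]])), 0L)
  expect_equal(nrow(read.delim(paths[["detailed"]])), 0L)
  expect_true(any(grepl("Representative terms (0)",
                        readLines(paths[["html"]]), fixed = TRUE)))
})

test_that("detailed rows = summary rows + represented on random fixtures", {
  for (seed in 1:8) {
    col <- random_collection(seed, n_terms = 25L)
    lists <- random_lists(col, 2L, seed + 500L)
    out <- make_outcome(col, lists)
    r <- group_source_ranks(out, lists)
    dir <- tempfile()
    paths <- write_reports(out, r, col, dir, "fx")
    summary <- read.delim(paths[["summary"]])
    detailed <- read.delim(paths[["detailed"]])
    n_repr <- sum(summary$n_represented)
    expect_equal(nrow(summary), length(out$groups))
    expect_equal(nrow(detailed), nrow(summary) + n_repr)
    # heatmap cell non-absent iff a group member occurs in that source
    for (g in out$groups) {
      members <- c(g$representative_id, g$represented_ids)
      for (l in lists) {
        expect_identical(is.na(r[g$representative_id, l$alias]),
                         !any(members %in% l$term_ids))
      }
    }
  }
})

test_that("barplot heights sum to the discarded-by-coverage count", {
  col <- random_collection(42, n_terms = 30L)
  lists <- random_lists(col, 2L, 4242)
  out <- make_outcome(col, lists)
  counts <- represented_counts(out)
  merged_n <- length(merge_rankings(lists)$term_ids)
  expect_equal(sum(counts),
               merged_n - length(out$groups) - length(out$undersized_ids) -
                 length(out$unannotated_ids) - length(out$oversized_ids))
})

test_that("figures are written for PNG and SVG and clamp top_n", {
  col <- micro_collection()
  lst <- ranked_term_list(c("B", "A", "C", "D"), "S")
  out <- make_outcome(col, list(lst))
  q <- assign_quartiles(group_source_ranks(out, list(lst)), list(lst))
  for (ext in c("png", "svg")) {
    hm <- tempfile(fileext = paste0(".", ext))
    bp <- tempfile(fileext = paste0(".", ext))
    render_heatmap(q, top_n = 50L, hm)   # clamped to 3 representatives
    render_barplot(out, top_n = 50L, bp)
    expect_gt(file.size(hm), 0)
    expect_gt(file.size(bp), 0)
  }
  p <- render_heatmap(q, top_n = 2L)
  expect_s3_class(p, "ggplot")
})

test_that("size/represented-count correlation behaves at the boundaries", {
  # strictly monotone: bigger terms represent more -> rho = 1
  sets <- list(R1 = sprintf("a%d", 1:30), R2 = sprintf("b%d", 1:20),
               R3 = sprintf("c%d", 1:10))
  kids <- c(lapply(1:3, function(i) sets$R1[i * 2 + (0:1)]),
            lapply(1:2, function(i) sets$R2[i * 2 + (0:1)]))
  names(kids) <- sprintf("k%d", seq_along(kids))
  col <- annotation_collection(c(sets, kids))
  lst <- ranked_term_list(c("R1", "R2", "R3", names(kids)), "S")
  out <- make_outcome(col, list(lst))
  expect_identical(representatives(out), c("R1", "R2", "R3"))
  res <- size_representation_correlation(out, col)
  expect_equal(res$rho, 1)
  # degenerate: all counts equal -> NA with warning
  col2 <- annotation_collection(list(A = sprintf("a%d", 1:5),
                                     B = sprintf("b%d", 1:6),
                                     C = sprintf("c%d", 1:7)))
  out2 <- make_outcome(col2, list(ranked_term_list(c("A", "B", "C"), "S")))
  expect_warning(res2 <- size_representation_correlation(out2, col2),
                 "zero variance")
  expect_true(is.na(res2$rho))
  # fewer than 3 representatives is an error
  out3 <- make_outcome(col2, list(ranked_term_list(c("A", "B"), "S")))
  expect_error(size_representation_correlation(out3, col2), "at least 3")
})
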
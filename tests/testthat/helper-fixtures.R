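# Shared fixtures and independent oracles.

# tiny collection used across modules: A covers C; B, D unrelated
micro_collection <- function() {
  annotation_collection(
    list(A = c("g1", "g2", "g3", "g4"),
         B = c("g1", "g2"),
         C = c("g3", "g4"),
         D = c("g5", "g6")),
    c(A = "broad term", B = "left child", C = "right child", D = "other branch"))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# random collection for round-trip and filtering properties; a mix of
# hierarchy-derived and fully random gene sets so coverage pairs both occur
# and are absent
random_collection <- function(seed, n_terms = 30L, universe = 60L) {
  set.seed(seed)
  genes <- sprintf("gene%03d", seq_len(universe))
  sets <- vector("list", n_terms)
  for (i in seq_len(n_terms)) {
    if (i > 1L && runif(1) < 0.4) {
      parent <- sets[[sample.int(i - 1L, 1L)]]
      sets[[i]] <- sample(parent, max(1L, ceiling(length(parent) * runif(1, 0.3, 0.9))))
    } else {
      sets[[i]] <- sample(genes, sample(1:20, 1L))
    }
  }
  names(sets) <- sprintf("R%03d", seq_len(n_terms))
  annotation_collection(sets)
}

# random ranked lists drawn from a collection's term IDs
random_lists <- function(collection, n_lists, seed) {
  set.seed(seed)
  ids <- names(collection$gene_sets)
  lapply(seq_len(n_lists), function(j) {
    k <- sample(seq(2L, length(ids)), 1L)
    ranked_term_list(sample(ids, k), paste0("src", j))
  })
}

# --- independent oracles -------------------------------------------------

# exact hypergeometric upper tail by log-space combinatorial summation
exact_hyper_tail <- function(k, K, n, N) {
  i <- k:min(K, n)
  if (k > min(K, n)) return(0)
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# naive reference filter: precompute the full pairwise coverage matrix by
# set-membership counting, then walk terms in order assigning each to the
# first earlier survivor that covers it
naive_filter <- function(term_ids, collection) {
  ids <- term_ids
  universe <- collection_universe(collection)
  M <- t(vapply(collection$gene_sets[ids],
                function(g) universe %in% g, logical(length(universe))))
  sizes <- rowSums(M)
  overlap <- M %*% t(M)                 # |Ai ∩ Aj|
  covers <- overlap == matrix(sizes, nrow = length(ids), ncol = length(ids))
  # covers[i, j]: term j covers term i (overlap equals i's size)
  rep_of <- rep(NA_integer_, length(ids))
  surviving <- logical(length(ids))
  for (i in seq_along(ids)) {
    hit <- which(surviving[seq_len(i - 1L)] & covers[i, seq_len(i - 1L)])
    if (length(hit) > 0L) {
      rep_of[i] <- hit[1L]
    } else {
      surviving[i] <- TRUE
    }
  }
  groups <- lapply(which(surviving), function(j) {
    list(representative_id = ids[j],
         represented_ids = ids[which(rep_of == j)])
  })
  groups
}

# flatten an outcome's groups for comparison with the oracle
group_structure <- function(groups) {
  lapply(groups, function(g) list(representative_id = g$representative_id,
                                  represented_ids = unname(g$represented_ids)))
}

# fixture ontology shared by the end-to-end ORA tests
fixture_ontology <- function() {
  generate_ontology(universe_size = 2000L, n_roots = 5L, depth = 4L,
                    branching = 3L, child_fraction = 0.5, seed = 424242L)
}
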
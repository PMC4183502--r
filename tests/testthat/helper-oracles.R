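# Independent mini-oracles used across test files.

# Direct enumeration of admissible placements of e points on the border
# region: cells whose column or row lies on one of the m distance-d grid
# lines per axis, with F open interior columns and F open interior rows
# available, one point per row/column.  Counts subsets of e cells with
# pairwise distinct rows and columns.  Independent of the package's
# closed-form border counts.
enumerate_border_placements <- function(e, F, m) {
  n_lines <- m + F # per axis: m new lines, F open interior lines
  cells <- expand.grid(col = seq_len(n_lines), row = seq_len(n_lines))
  border <- cells[cells$col <= m | cells$row <= m, ]
  if (e == 0L) return(1L)
  if (e > nrow(border)) return(0L)
  combos <- utils::combn(nrow(border), e)
  ok <- 0L
  for (j in seq_len(ncol(combos))) {
    sub <- border[combos[, j], ]
    if (!anyDuplicated(sub$col) && !anyDuplicated(sub$row)) ok <- ok + 1L
  }
  ok
}

# Empirical probability of a distance prefix from an enumeration object.
oracle_prefix_prob <- function(oracle, prefix) {
  len <- length(prefix)
  hits <- apply(oracle$distances[, seq_len(len), drop = FALSE], 1L,
                function(z) all(z == prefix))
  sum(hits) / oracle$total
}

# Exact conditional law of the next distance given a full history, from an
# enumeration object (counts are exact integers).
oracle_conditional <- function(oracle, history) {
  len <- length(history)
  sel <- apply(oracle$distances[, seq_len(len), drop = FALSE], 1L,
               function(z) all(z == history))
  stopifnot(any(sel))
  nxt <- oracle$distances[sel, len + 1L]
  tabulate(nxt, nbins = oracle$n %/% 2L) / sum(sel)
}

# Both package statistics from one shared profile.
both_statistics <- function(pp, i_max) {
  pr <- nn_distance_profile(pp, i_max)
  c(chisq = aggregate_chisq(lapply(seq_len(i_max),
                                   function(i) chisq_test(pr, i))),
    extreme = extreme_test(pr)$E)
}
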
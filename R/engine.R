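# Internal sweep engine shared by de novo clustering (opticlust) and the
# fit phase of reference-based clustering (optifit).
#
# State is kept in flat vectors for speed:
#   memb  — integer OTU id per sequence (aligned with graph$ids)
#   sizes — OTU sizes indexed by OTU id (0 = dead/empty OTU)
#   conf  — c(tp, fp, fn, tn), updated exactly per accepted move
# Candidate moves for a sequence are the OTUs holding at least one of its
# neighbors, its current OTU ("stay"), and a brand-new singleton.  Each
# candidate's confusion counts follow from local arithmetic (see
# move_delta()), so a move costs O(degree + |current OTU| + |target OTU|).
# Ties within MCC_TIE_TOL are broken uniformly at random; "stay" can only
# win through this tie-break, never by default.
#
# The engine consumes the current RNG stream (callers seed it), visits
# movable sequences in a freshly shuffled order every sweep, and stops
# when the sweep-over-sweep MCC gain drops to `tolerance` or the sweep
# cap is reached.  MCC is monotone non-decreasing over accepted moves;
# this is asserted in-run.

run_sweeps <- function(graph, memb, sizes, conf, movable,
                       ref_otu_max = Inf, tolerance = 1e-4,
                       max_iterations = 100, next_otu = NULL) {
  adj <- graph$adj
  if (is.null(next_otu)) next_otu <- length(sizes) + 1L
  sizes <- c(sizes, numeric(16))  # headroom for new singleton OTUs
  mcc_now <- mcc_num(conf[1], conf[2], conf[3], conf[4])
  iterations <- 0L
  converged <- FALSE
  trace <- mcc_now  # MCC after every accepted move, starting state first

  while (iterations < max_iterations) {
    mcc_prev <- mcc_now
    order <- movable[sample.int(length(movable))]
    for (i in order) {
      cur <- memb[i]
      nb <- adj[[i]]
      om <- memb[nb]
      cand <- unique(om)
      kvec <- tabulate(match(om, cand))
      pos_cur <- match(cur, cand)
      k_cur <- if (is.na(pos_cur)) 0 else kvec[pos_cur]
      m_cur <- sizes[cur] - 1 - k_cur
      # counts with i carved out as a singleton
      tp0 <- conf[1] - k_cur; fp0 <- conf[2] - m_cur
      fn0 <- conf[3] + k_cur; tn0 <- conf[4] + m_cur
      keep <- cand != cur & cand <= ref_otu_max
      tgt <- cand[keep]
      kt <- kvec[keep]
      st <- sizes[tgt]
      opt_mcc <- c(
        mcc_now,                                    # 1: stay
        mcc_num(tp0, fp0, fn0, tn0),                # 2: new singleton
        mcc_num(tp0 + kt, fp0 + (st - kt), fn0 - kt, tn0 - (st - kt)))
      if (sizes[cur] == 1) opt_mcc[2] <- -Inf       # singleton == stay
      best <- max(opt_mcc)
      if (best < mcc_now - MCC_TIE_TOL) {
        abort("internal error: best candidate MCC below current MCC")
      }
      hits <- which(opt_mcc >= best - MCC_TIE_TOL)
      pick <- if (length(hits) == 1) hits else
        hits[sample.int(length(hits), 1)]
      if (pick == 1) next
      sizes[cur] <- sizes[cur] - 1
      if (pick == 2) {
        if (next_otu > length(sizes)) sizes <- c(sizes, numeric(length(sizes)))
        memb[i] <- next_otu
        sizes[next_otu] <- 1
        next_otu <- next_otu + 1L
        conf <- c(tp0, fp0, fn0, tn0)
        mcc_now <- opt_mcc[2]
      } else {
        t <- tgt[pick - 2]
        k <- kt[pick - 2]
        m <- st[pick - 2] - k
        memb[i] <- t
        sizes[t] <- sizes[t] + 1
        conf <- c(tp0 + k, fp0 + m, fn0 - k, tn0 - m)
        mcc_now <- opt_mcc[pick]
      }
      trace <- c(trace, mcc_now)
    }
    iterations <- iterations + 1L
    if (mcc_now - mcc_prev <= tolerance) {
      converged <- TRUE
      break
    }
  }
  list(memb = memb, sizes = sizes, conf = conf, mcc = mcc_now,
       iterations = iterations, converged = converged, next_otu = next_otu,
       mcc_trace = trace)
}
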
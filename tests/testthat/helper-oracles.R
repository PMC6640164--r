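# Independent brute-force implementations used as oracles. These are
# written as literal per-position scans, deliberately sharing no code with
# the package internals.

oracle_call_tss <- function(tex, notex, params, circular = FALSE) {
  res <- list()
  for (s in c("+", "-")) {
    tv <- if (s == "+") tex$five_prime_plus else tex$five_prime_minus
    nv <- if (s == "+") notex$five_prime_plus else notex$five_prime_minus
    L <- length(tv)
    w <- params$cluster_width
    cand <- integer(0)
    for (p in seq_len(L)) {
      if (tv[p] < params$min_height) next
      if (tv[p] / (nv[p] + params$pseudocount) < params$min_enrichment) next
      win <- (p - w):(p + w)
      win <- if (circular) ((win - 1) %% L) + 1 else win[win >= 1 & win <= L]
      if (tv[p] < max(tv[win])) next
      cand <- c(cand, p)
    }
    # merge runs closer than w, keep max count, tie -> leftmost
    while (length(cand)) {
      run <- cand[1]
      rest <- cand[-1]
      while (length(rest) && rest[1] - run[length(run)] <= w) {
        run <- c(run, rest[1])
        rest <- rest[-1]
      }
      best <- run[which.max(tv[run])]
      res[[length(res) + 1L]] <- data.frame(
        position = best, strand = s, tex_height = tv[best],
        notex_height = nv[best],
        enrichment = tv[best] / (nv[best] + params$pseudocount),
        stringsAsFactors = FALSE)
      cand <- rest
    }
  }
  if (!length(res)) {
    return(data.frame(position = integer(), strand = character(),
                      tex_height = numeric(), notex_height = numeric(),
                      enrichment = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_antisense_fraction <- function(position, strand, tex,
                                      half_window = 400L,
                                      upstream_window = 100L) {
  av <- if (strand == "+") tex$five_prime_minus else tex$five_prime_plus
  L <- length(av)
  num <- 0; den <- 0
  for (o in c(-half_window:-1, 1:half_window)) {
    p <- if (strand == "+") position + o - (o > 0) else position - o + (o > 0)
    p <- ((p - 1) %% L) + 1
    den <- den + av[p]
    if (o >= -upstream_window && o <= -1) num <- num + av[p]
  }
  if (den == 0) 0 else num / den
}

# Sparse random 5'-end track pair for property tests.
random_track_pair <- function(L, n_spikes = 12, max_height = 80) {
  mk <- function() {
    v <- numeric(L)
    at <- sample.int(L, n_spikes)
    v[at] <- sample.int(max_height, n_spikes, replace = TRUE)
    v
  }
  tex <- coverage_track("TEX", L, five_prime_plus = mk(),
                        five_prime_minus = mk())
  notex <- coverage_track("NOTEX", L,
                          five_prime_plus = round(mk() / 8),
                          five_prime_minus = round(mk() / 8))
  list(tex = tex, notex = notex)
}

# Reverse complement of a pwm (swap strands and reverse columns).
rc_pwm <- function(pwm) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- unclass(pwm)[comp[rownames(pwm)], rev(seq_len(ncol(pwm)))]
  rownames(m) <- names(comp)
  structure(m, class = "pwm", anchor_offset = attr(pwm, "anchor_offset"),
            offsets = attr(pwm, "offsets"),
            pseudocount = attr(pwm, "pseudocount"), n = attr(pwm, "n"))
}
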
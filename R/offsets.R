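# Promoter coordinate convention: offsets relative to a TSS have no zero.
# The transcribed start base is +1, the base immediately upstream is -1, so
# element annotations such as "TATA box -30..-23" follow the convention used
# throughout archaeal promoter work.

# The ordered offset vector from `from` to `to`, skipping 0.
offset_seq <- function(from, to) {
  stopifnot(from <= to, from != 0L, to != 0L)
  setdiff(seq.int(from, to), 0L)
}

# Map TSS-relative offsets to genomic positions (unwrapped; may fall outside
# [1, len] and is wrapped later for circular replicons). Offsets ascend
# 5'->3' toward and through the TSS on the TSS's own strand.
offset_to_genomic <- function(tss_pos, strand, offsets) {
  if (strand == "+") {
    tss_pos + offsets - (offsets > 0L)
  } else {
    tss_pos - offsets + (offsets > 0L)
  }
}

# Inverse mapping: genomic position -> TSS-relative offset (no zero).
genomic_to_offset <- function(tss_pos, strand, positions) {
  d <- if (strand == "+") positions - tss_pos else tss_pos - positions
  ifelse(d >= 0L, d + 1L, d)
}

# Walk `len` consecutive no-zero offsets ending at `end` (inclusive),
# e.g. element_offsets(-23, 8) == -30:-23.
element_offsets <- function(end, len) {
  out <- integer(len)
  o <- end
  for (i in seq.int(len, 1L)) {
    out[i] <- o
    o <- o - 1L
    if (o == 0L) o <- -1L
  }
  out
}
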
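# Abstract assignment instances (keys with unique stats + multi-candidate
# fragments), used for property tests and for cross-checking the EM against
# the loop-explicit reference implementation in helper-oracle.R.

randomInstance <- function(seed, maxLoci = 10, maxFrags = 100) {
  set.seed(seed)
  k <- sample(2:maxLoci, 1)
  keys <- sprintf("L%02d", seq_len(k))
  C_U <- stats::setNames(sample(0:5, k, replace = TRUE), keys)
  L_U <- stats::setNames(
    mapply(function(cu) if (cu > 0) sample(seq_len(cu), 1) else 0L, C_U),
    keys)
  C_fixed <- C_U + stats::setNames(sample(0:2, k, replace = TRUE), keys)
  l <- stats::setNames(sample(100:5000, k, replace = TRUE), keys)
  nf <- sample(1:maxFrags, 1)
  sizes <- sample(rep(2:min(4, k), length.out = 3), nf, replace = TRUE)
  frags <- lapply(seq_len(nf), function(i) sample(keys, sizes[i]))
  names(frags) <- sprintf("f%03d", seq_len(nf))
  list(keys = keys, C_U = C_U, L_U = L_U, C_fixed = C_fixed, l = l,
       frags = frags)
}

instToTables <- function(inst) {
  ustats <- data.table::data.table(
    locus_id = inst$keys, orientation = "sense",
    C_U = as.integer(inst$C_U), L_U = as.integer(inst$L_U),
    C_fixed = as.numeric(inst$C_fixed))
  lengths <- data.table::data.table(
    locus_id = inst$keys, orientation = "sense", l_TE = as.numeric(inst$l))
  cand <- data.table::rbindlist(lapply(names(inst$frags), function(fid) {
    data.table::data.table(frag_id = fid, locus_id = inst$frags[[fid]],
                           orientation = "sense")
  }))
  list(ustats = ustats, lengths = lengths, cand = cand)
}

# named per-key count vector from a runEM() result
countsVec <- function(em, keys) {
  v <- stats::setNames(em$counts$C_TE, em$counts$locus_id)
  unname(v[keys])
}
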
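# Shared helpers: tiny in-code fixtures and independent brute-force oracles.

# small expression matrix with explicit values
tiny_matrix <- function(vals = 1:6, genes = c("g1", "g2", "g3"),
                        samples = c("s1", "s2")) {
  matrix(as.numeric(vals), nrow = length(genes),
         dimnames = list(genes, samples))
}

# one complete trio design
tiny_design <- function(pair = "pA") {
  as_design(data.frame(
    sample_id = c("msc", "ch", "co"),
    role = c("msc_mono", "ch_mono", "coculture"),
    pair_id = pair, sex = c("male", "female", "mixed"),
    seeded_fraction = 0.8, stringsAsFactors = FALSE))
}

# trio matrix builder: named vectors of per-gene values
trio_matrix <- function(msc, ch, co) {
  genes <- names(msc)
  matrix(c(msc, ch, co), nrow = length(genes),
         dimnames = list(genes, c("msc", "ch", "co")))
}

# independent brute-force Venn oracle over call-set lists: for every
# non-empty subset of pairs, the genes in ALL subset members and NONE of the
# others, via plain set operations
brute_force_venn <- function(sets) {
  n <- length(sets)
  out <- list()
  for (m in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    inside <- Reduce(intersect, sets[idx])
    for (j in setdiff(seq_len(n), idx)) inside <- setdiff(inside, sets[[j]])
    out[[paste(names(sets)[idx], collapse = "&")]] <- sort(inside)
  }
  out
}

# printed marker-table reference values (RPKM and ratio columns)
table1_printed_ratios <- function() {
  list(
    A211 = c(RPS4Y1 = 62.54994, DDX3Y = 55.6573, PRKY = 50.55364,
             USP9Y = 52.5296, KDM5D = 73.88392, ZFY = 52.67286,
             EIF1AY = 53.05829),
    A283 = c(RPS4Y1 = 47.06513, DDX3Y = 54.80805, PRKY = 57.85934,
             USP9Y = 58.32615, KDM5D = 64.34326, ZFY = 53.99662,
             EIF1AY = 61.89636))
}
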
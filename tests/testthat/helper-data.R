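# In-code builders for small file fixtures.

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tiny_ingredient_tsv <- function() {
  write_tmp(c(
    "mol_id\tname\tmw\tob\tdl\tpart",
    "MOL000546\tDiosgenin\t414.69\t80.88\t0.81\tleaves stems",
    "MOL999001\tlowball\t200.5\t12.0\t0.50\tfruits",
    "MOL999002\tflatline\t310.0\t45.0\t0.05\troots"
  ))
}

tiny_pair_tsv <- function() {
  write_tmp(c(
    "mol_id\tgene",
    "i1\tTP53",
    "i1\ttp53",      # duplicate after normalization
    "i1\tEGFR",
    "i2\tEGFR",
    "i2\tIL6"
  ))
}

tiny_gmt <- function() {
  write_tmp(c(
    "hsa05219\tBladder cancer\tTP53\tEGFR",
    "hsa04010\tMAPK signaling pathway\tIL6\tEGFR\tMYC"
  ), ext = ".gmt")
}

# a deterministic annotation collection built in memory
mini_annotation <- function() {
  annotation_collection(
    list(
      T1 = list(name = "alpha", genes = c("A", "B", "C", "D")),
      T2 = list(name = "beta", genes = c("C", "D", "E", "F", "G")),
      T3 = list(name = "gamma", genes = c("H", "I"))
    ),
    category = "TEST"
  )
}
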
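# Shared fixtures: tiny catalogs built in code and random-input generators.

# TspGWI / BspGI plus a palindromic cutter, suppliers non-empty.
paper_catalog <- function() {
  enzyme_catalog(
    name = c("TspGWI", "BspGI", "EcoRI"),
    recognition = c("ACGGA", "CTGGAC", "G^AATTC"),
    microorganism = c("Thermus sp. GW", "Bacillus sphaericus",
                      "Escherichia coli RY13"),
    source = c("S. Gray", "ATCC 4525", "R.N. Yoshimori"),
    suppliers = c("Q", "N", "B"),
    references = list("ref A", "ref B", "ref C"))
}

# BspGI plus degenerate-pattern enzymes whose sites straddle the variation of
# AATTTCTGG[A/G]CCCTAACGGT and match the A allele only.
iupac_site_catalog <- function() {
  enzyme_catalog(
    name = c("TspGWI", "BspGI", "DegI", "DegII", "DegIII"),
    recognition = c("ACGGA", "CTGGAC", "YTGGAC", "CTGGAY", "MTGGAC"),
    suppliers = c("Q", "N", "", "", "K"))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rand_iupac_pattern <- function(m, p_degenerate = 0.25) {
  letters15 <- names(iupac_bases())
  w <- c(rep(1 - p_degenerate, 4) / 4, rep(p_degenerate, 11) / 11)
  paste(sample(letters15, m, replace = TRUE, prob = w), collapse = "")
}

# random bracket template: backbone of length n with k substitution sites
rand_template <- function(n = 40, k = 1, allow_indel = FALSE) {
  pos <- sort(sample(seq_len(n), k))
  ch <- strsplit(rand_dna(n), "")[[1]]
  out <- character(0)
  last <- 0
  for (p in pos) {
    seg <- if (p - 1 >= last + 1) paste(ch[(last + 1):(p - 1)], collapse = "") else ""
    al <- sample(c("A", "C", "G", "T"), sample(2:4, 1))
    if (allow_indel && stats::runif(1) < 0.3)
      al <- c("-", paste(sample(c("A", "C", "G", "T"), sample(1:3, 1),
                                replace = TRUE), collapse = ""))
    out <- c(out, seg, paste0("[", paste(al, collapse = "/"), "]"))
    last <- p
  }
  out <- c(out, if (last < n) paste(ch[(last + 1):n], collapse = "") else "")
  parse_input(paste(out, collapse = ""), dialect = "bracket")
}
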
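# Amino-acid alphabet, substitution matrix and genetic-code reachability.

#' The 20 standard amino acids (1-letter codes)
#'
#' @return Character vector of length 20, in the conventional
#'   BLOSUM row order (A R N D C Q E G H I L K M F P S T W Y V).
#' @export
amino_acids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

# Canonical NCBI BLOSUM62, 20 x 20 integer block (no ambiguity codes).
.blosum62 <- local({
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  m <- matrix(c(
    4,-1,-2,-2,0,-1,-1,0,-2,-1,-1,-1,-1,-2,-1,1,0,-3,-2,0,
    -1,5,0,-2,-3,1,0,-2,0,-3,-2,2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2,0,6,1,-3,0,0,0,1,-3,-3,0,-2,-3,-2,1,0,-4,-2,-3,
    -2,-2,1,6,-3,0,2,-1,-1,-3,-4,-1,-3,-3,-1,0,-1,-4,-3,-3,
    0,-3,-3,-3,9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1,1,0,0,-3,5,2,-2,0,-3,-2,1,0,-3,-1,0,-1,-2,-1,-2,
    -1,0,0,2,-4,2,5,-2,0,-3,-3,1,-2,-3,-1,0,-1,-3,-2,-2,
    0,-2,0,-1,-3,-2,-2,6,-2,-4,-4,-2,-3,-3,-2,0,-2,-2,-3,-3,
    -2,0,1,-1,-3,0,0,-2,8,-3,-3,-1,-2,-1,-2,-1,-2,-2,2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3,4,2,-3,1,0,-3,-2,-1,-3,-1,3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3,2,4,-2,2,0,-3,-2,-1,-2,-1,1,
    -1,2,0,-1,-3,1,1,-2,-1,-3,-2,5,-1,-3,-1,0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1,0,-2,-3,-2,1,2,-1,5,0,-2,-1,-1,-1,-1,1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1,0,0,-3,0,6,-4,-2,-2,1,3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4,7,-1,-1,-4,-3,-2,
    1,-1,1,0,-1,0,0,0,-1,-2,-2,0,-1,-2,-1,4,1,-3,-2,-2,
    0,-1,0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1,1,5,-2,-2,0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1,1,-4,-3,-2,11,2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3,2,-1,-1,-2,-1,3,-3,-2,-2,2,7,-1,
    0,-3,-3,-3,-1,-2,-2,-3,-3,3,1,-2,1,-1,-2,-2,0,-3,-1,4),
    nrow = 20, byrow = TRUE, dimnames = list(aa, aa))
  storage.mode(m) <- "integer"
  m
})

#' BLOSUM62 element for an amino-acid replacement
#'
#' Looks up the log-odds substitution score of the canonical 20 x 20
#' BLOSUM62 matrix for a native/variant residue pair.  The matrix is
#' symmetric, so the argument order does not matter.
#'
#' @param native_aa,variant_aa 1-letter amino-acid codes (vectorised;
#'   recycled to a common length).
#' @return Integer vector of substitution scores in \[-4, 11\].
#' @examples
#' blosum62_element("W", "W")  # 11
#' blosum62_element("D", "E")  # 2
#' @export
blosum62_element <- function(native_aa, variant_aa) {
  native_aa <- toupper(as.character(native_aa))
  variant_aa <- toupper(as.character(variant_aa))
  bad <- !(native_aa %in% amino_acids()) | !(variant_aa %in% amino_acids())
  if (any(bad)) {
    stop("non-standard amino acid code(s): ",
         paste(unique(c(native_aa[bad], variant_aa[bad])), collapse = ", "))
  }
  .blosum62[cbind(native_aa, variant_aa)]
}

# 20 x 20 logical matrix: is aa1 -> aa2 reachable by a single nucleotide
# change in at least one codon of aa1?  Built once from the standard
# genetic code, cached.
snv_reachability <- function() {
  if (!is.null(.prdis_env$snv_reach)) {
    return(.prdis_env$snv_reach)
  }
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  aa <- amino_acids()
  reach <- matrix(FALSE, 20, 20, dimnames = list(aa, aa))
  for (c1 in codons) {
    a1 <- code[[c1]]
    if (!a1 %in% aa) next
    s1 <- strsplit(c1, "")[[1]]
    for (pos in 1:3) {
      for (nt in c("A", "C", "G", "T")) {
        if (nt == s1[pos]) next
        s2 <- s1
        s2[pos] <- nt
        a2 <- code[[paste(s2, collapse = "")]]
        if (a2 %in% aa && a2 != a1) reach[a1, a2] <- TRUE
      }
    }
  }
  .prdis_env$snv_reach <- reach
  reach
}
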
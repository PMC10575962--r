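# small shared helpers; not exported

BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_dna <- function(x) grepl("^[ACGT]+$", x)

# Phred+33 string <-> integer vector
qual_to_phred <- function(q) utf8ToInt(q) - 33L
phred_to_qual <- function(p) intToUtf8(p + 33L)

# reverse a quality string (pairs with reverse-complementing the sequence)
rev_qual <- function(q) {
  vapply(q, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

# report-style rounding: half away from zero, matching printed percentages
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(charToRaw(a) != charToRaw(b))
}

CODON_TABLE <- local({
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  # standard genetic code in TCAG order
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  setNames(aa, codons)
})

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

translate_codon <- function(codon) unname(CODON_TABLE[codon])

aa_three <- function(a) unname(AA3[a])
aa_one <- function(a3) names(AA3)[match(a3, AA3)]
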
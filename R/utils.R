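# Internal helpers shared across modules.
#
# Sequences are held in two forms: character strings at the file boundary and
# integer vectors internally (A=1, C=2, G=3, T=4, N=5).  All heavy per-site
# arithmetic runs on the integer form.

BASES <- c("A", "C", "G", "T")
N_CODE <- 5L

# lookup table indexed by utf8 code point + 1
.base_lut <- local({
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt("A") + 1L] <- 1L
  lut[utf8ToInt("C") + 1L] <- 2L
  lut[utf8ToInt("G") + 1L] <- 3L
  lut[utf8ToInt("T") + 1L] <- 4L
  lut[utf8ToInt("N") + 1L] <- 5L
  lut[utf8ToInt("a") + 1L] <- 1L
  lut[utf8ToInt("c") + 1L] <- 2L
  lut[utf8ToInt("g") + 1L] <- 3L
  lut[utf8ToInt("t") + 1L] <- 4L
  lut[utf8ToInt("n") + 1L] <- 5L
  lut
})

dna_to_int <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  code <- .base_lut[utf8ToInt(s) + 1L]
  if (anyNA(code)) {
    bad <- which(is.na(code))[1L]
    stop("non-IUPAC character '", substr(s, bad, bad), "' at position ", bad)
  }
  code
}

int_to_dna <- function(x) {
  intToUtf8(c(utf8ToInt("A"), utf8ToInt("C"), utf8ToInt("G"),
              utf8ToInt("T"), utf8ToInt("N"))[x])
}

#' @noRd
chrom_classes <- c("autosome", "X", "Y", "unplaced")

assert_chrom_class <- function(x) {
  if (!all(x %in% chrom_classes)) {
    stop("chrom_class must be one of: ", paste(chrom_classes, collapse = ", "))
  }
  x
}

# Derive a reproducible sub-seed for a named stage from a master seed, so each
# module consumes an independent stream but the whole run is a function of one
# seed.  Kept below 2^31 - 1.
substream_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629)
}

# complement in integer code space (N maps to N)
complement_int <- function(x) c(4L, 3L, 2L, 1L, 5L)[x]

`%||%` <- function(a, b) if (is.null(a)) b else a
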
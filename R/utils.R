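# Internal helpers: base encoding, complements, condition constructors.

RIBO_BASES <- c("A", "C", "G", "U")

# A=0, C=1, G=2, U=3 (matches the C++ core)
.seqToInt <- function(x) {
  v <- match(strsplit(toupper(x), "")[[1]], RIBO_BASES) - 1L
  if (anyNA(v)) {
    stop(.inputError(sprintf(
      "invalid residue(s) in sequence '%s': alphabet is A, C, G, U",
      substr(x, 1L, 40L)
    )))
  }
  v
}

.intToSeq <- function(v) paste(RIBO_BASES[v + 1L], collapse = "")

# Watson-Crick complement on the integer encoding (A<->U, C<->G)
.compInt <- function(v) 3L - v

.revCompInt <- function(v) rev(3L - v)

.isWCInt <- function(a, b) (a + b) == 3L

# Runs of identical bases of length >= maxRun are forbidden unless the
# run lies entirely inside protected (motif/fixed) positions, so that
# fixed elements such as poly(U) terminator tails remain legal.
.hasIllegalRun <- function(v, protected, maxRun = 4L) {
  n <- length(v)
  if (n < maxRun) return(FALSE)
  if (is.null(protected)) protected <- rep(FALSE, n)
  runStart <- 1L
  for (i in 2L:(n + 1L)) {
    if (i > n || v[i] != v[runStart]) {
      if (i - runStart >= maxRun && !all(protected[runStart:(i - 1L)])) {
        return(TRUE)
      }
      runStart <- i
    }
  }
  FALSE
}

.inputError <- function(msg) {
  errorCondition(msg, class = c("riboforge_input_error", "riboforge_error"))
}

.specError <- function(msg) {
  errorCondition(msg, class = c("riboforge_spec_error", "riboforge_error"))
}

.capabilityError <- function(msg) {
  errorCondition(msg, class = c("riboforge_capability_error", "riboforge_error"))
}

.paramError <- function(msg) {
  errorCondition(msg, class = c("riboforge_parameter_error", "riboforge_error"))
}
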
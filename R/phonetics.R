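# Surname normalization and American Soundex coding.
#
# Soundex is the blocking key for linkage: spelling variants of the same
# spoken name (hyphen/space differences, -ian/-yan swaps, truncated forms)
# should land in the same block so that they are ever compared at all.

# transliteration map applied before iconv, so the common Latin-1/Latin-2
# accented letters survive even where iconv's //TRANSLIT is conservative
.DIACRITICS_FROM <- "àáâãäåçèéêëìíîïñòóôõöùúûüýÀÁÂÃÄÅÇÈÉÊËÌÍÎÏÑÒÓÔÕÖÙÚÛÜÝšŠžŽčČ"
.DIACRITICS_TO   <- "aaaaaaceeeeiiiinooooouuuuyAAAAAACEEEEIIIINOOOOOUUUUYsSzZcC"

#' Normalize a surname for phonetic comparison
#'
#' Uppercases, transliterates diacritics to ASCII, and strips everything that
#' is not a letter (spaces, hyphens, apostrophes, periods, digits). Hyphen,
#' space and case variants of a surname therefore normalize identically, e.g.
#' `"Ter-Minasyan"` and `"Ter Minasyan"` both become `"TERMINASYAN"`.
#' Normalization is idempotent.
#'
#' @param x character vector of raw surnames.
#' @return character vector of normalized surnames (uppercase `A`-`Z` only).
#'   An input with no letters at all is a degenerate input and raises an error.
#' @examples
#' normalize_surname(c("Ter-Minasyan", "Ter Minasyan"))
#' surname_letters("O'Brien")  # 6
#' @seealso [soundex()], [surname_letters()]
#' @export
normalize_surname <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  out <- chartr(.DIACRITICS_FROM, .DIACRITICS_TO, x)
  out <- suppressWarnings(iconv(out, from = "", to = "ASCII//TRANSLIT"))
  out[is.na(out)] <- x[is.na(out)]
  out <- toupper(out)
  out <- gsub("[^A-Z]", "", out)
  bad <- !is.na(x) & !nzchar(out)
  if (any(bad)) {
    stop("degenerate surname(s) with no letters: ",
         paste(sQuote(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Count the letters of a surname
#'
#' Letter count of the normalized form: punctuation, spaces and digits are
#' excluded, so length-based filter rules neither rescue nor doom a name on
#' account of a hyphen.
#'
#' @param x character vector of raw surnames.
#' @return integer vector of letter counts.
#' @export
surname_letters <- function(x) {
  nchar(normalize_surname(x), type = "chars")
}

# per-letter Soundex digit codes; vowels+Y -> 0 (separator), H/W -> NA (ignored)
.SOUNDEX_CODE <- local({
  code <- rep(NA_integer_, 26)
  names(code) <- LETTERS
  code[c("B", "F", "P", "V")] <- 1L
  code[c("C", "G", "J", "K", "Q", "S", "X", "Z")] <- 2L
  code[c("D", "T")] <- 3L
  code["L"] <- 4L
  code[c("M", "N")] <- 5L
  code["R"] <- 6L
  code[c("A", "E", "I", "O", "U", "Y")] <- 0L
  code  # H, W stay NA
})

soundex_one <- function(name) {
  letters_vec <- strsplit(name, "", fixed = TRUE)[[1]]
  codes <- .SOUNDEX_CODE[letters_vec]
  digits <- integer(0)
  # previous emitted/seen code; letters separated only by H or W are treated
  # as adjacent (their codes collapse), vowels break the adjacency
  prev <- codes[[1]]
  if (is.na(prev)) prev <- -1L  # leading H/W: next consonant always emits
  for (i in seq_along(codes)[-1]) {
    cd <- codes[[i]]
    if (is.na(cd)) next            # H or W: invisible to adjacency
    if (cd == 0L) { prev <- 0L; next }  # vowel: resets adjacency
    if (!identical(cd, prev)) digits <- c(digits, cd)
    prev <- cd
    if (length(digits) >= 3L) break
  }
  paste0(letters_vec[[1]],
         paste(c(digits, 0L, 0L, 0L)[1:3], collapse = ""))
}

#' American Soundex code of a surname
#'
#' Standard American Soundex: keep the first letter, code the remaining
#' consonants (B,F,P,V=1; C,G,J,K,Q,S,X,Z=2; D,T=3; L=4; M,N=5; R=6), drop
#' vowels and Y, collapse runs of equal codes, and treat letters separated
#' only by H or W as adjacent; pad or truncate to one letter plus three
#' digits. Input is normalized first (see [normalize_surname()]), so
#' punctuation and case never change the code.
#'
#' @param x character vector of surnames (raw or already normalized).
#' @return character vector of 4-character codes matching `^[A-Z][0-9]{3}$`.
#' @examples
#' soundex(c("Robert", "Rupert"))        # both "R163"
#' soundex("Haroutunia") == soundex("Haroutunian")
#' @export
soundex <- function(x) {
  vapply(normalize_surname(x), soundex_one, character(1), USE.NAMES = FALSE)
}

#' Do two surnames share a Soundex block?
#'
#' Symmetric, reflexive test used for candidate-pair blocking: `TRUE` iff the
#' two names code identically under [soundex()] after normalization.
#'
#' @param a,b character vectors of surnames (recycled to common length).
#' @return logical vector.
#' @examples
#' same_block("Mahtesyan", "Mahtesian")     # TRUE
#' same_block("Ter-Minasyan", "Ter Minasyan")
#' @export
same_block <- function(a, b) {
  soundex(a) == soundex(b)
}

#' Jaro-Winkler similarity between two strings
#'
#' Classic Jaro similarity (matches within half the longer length, minus one;
#' transposition penalty) with the Winkler common-prefix boost (scaling factor
#' 0.1, prefix capped at 4). Used to score non-exact, non-truncation candidate
#' pairs during linkage; operates on whatever strings it is given, so callers
#' normalize first.
#'
#' @param a,b character vectors (recycled to common length).
#' @param prefix_scale Winkler prefix scaling factor, default 0.1.
#' @return numeric vector of similarities in `[0, 1]`.
#' @examples
#' jaro_winkler("MARTHA", "MARHTA")  # 0.9611
#' @export
jaro_winkler <- function(a, b, prefix_scale = 0.1) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  vapply(seq_len(n), function(i) jw_one(a[[i]], b[[i]], prefix_scale),
         numeric(1))
}

jw_one <- function(s1, s2, prefix_scale) {
  if (identical(s1, s2)) return(1)
  c1 <- strsplit(s1, "", fixed = TRUE)[[1]]
  c2 <- strsplit(s2, "", fixed = TRUE)[[1]]
  l1 <- length(c1); l2 <- length(c2)
  if (l1 == 0L || l2 == 0L) return(0)
  window <- max(max(l1, l2) %/% 2L - 1L, 0L)
  m1 <- logical(l1); m2 <- logical(l2)
  m <- 0L
  for (i in seq_len(l1)) {
    lo <- max(1L, i - window); hi <- min(l2, i + window)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!m2[j] && c1[i] == c2[j]) {
        m1[i] <- TRUE; m2[j] <- TRUE; m <- m + 1L
        break
      }
    }
  }
  if (m == 0L) return(0)
  t <- sum(c1[m1] != c2[m2]) / 2
  jaro <- (m / l1 + m / l2 + (m - t) / m) / 3
  p <- 0L
  for (k in seq_len(min(4L, l1, l2))) {
    if (c1[k] == c2[k]) p <- k else break
  }
  jaro + p * prefix_scale * (1 - jaro)
}
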
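#' Porter stemmer
#'
#' Reduces an English word to its root using the classic Porter (1980)
#' suffix-stripping algorithm in its original rule set.  This is the
#' stemmer whose surface forms ("apoptosi", "memori", "failur", "cognit")
#' appear throughout biomedical topic-model vocabularies.
#'
#' Words of two characters or fewer, and tokens containing characters
#' outside `[a-z]`, are returned unchanged: the algorithm is defined on
#' lowercase alphabetic words, and pass-through keeps pseudo-word tokens
#' (e.g. `"w0042"`) stable under stemming.
#'
#' @param words character vector of lowercase tokens.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("apoptosis", "memory", "failure", "cognition"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  vapply(words, porter_stem1, character(1), USE.NAMES = FALSE)
}

porter_stem1 <- function(word) {
  if (nchar(word) <= 2L || grepl("[^a-z]", word)) {
    return(word)
  }
  w <- strsplit(word, "", fixed = TRUE)[[1L]]
  w <- pt_step1a(w)
  w <- pt_step1b(w)
  w <- pt_step1c(w)
  w <- pt_step2(w)
  w <- pt_step3(w)
  w <- pt_step4(w)
  w <- pt_step5(w)
  paste(w, collapse = "")
}

# TRUE where the letter acts as a consonant.  'y' is a consonant at the
# start of the word or after a vowel, a vowel after a consonant.
pt_cons <- function(w) {
  n <- length(w)
  cons <- !(w %in% c("a", "e", "i", "o", "u"))
  for (i in seq_len(n)) {
    if (w[i] == "y") {
      cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
    }
  }
  cons
}

# The measure m of the stem: number of VC sequences in [C](VC)^m[V].
pt_measure <- function(w) {
  if (length(w) == 0L) return(0L)
  cons <- pt_cons(w)
  r <- rle(cons)$values
  # count transitions vowel-run -> consonant-run
  sum(!r[-length(r)] & r[-1L])
}

pt_has_vowel <- function(w) {
  length(w) > 0L && any(!pt_cons(w))
}

pt_double_cons <- function(w) {
  n <- length(w)
  n >= 2L && w[n] == w[n - 1L] && pt_cons(w)[n]
}

# *o: stem ends consonant-vowel-consonant, final consonant not w, x or y.
pt_cvc <- function(w) {
  n <- length(w)
  if (n < 3L) return(FALSE)
  cons <- pt_cons(w)
  cons[n] && !cons[n - 1L] && cons[n - 2L] && !(w[n] %in% c("w", "x", "y"))
}

pt_ends <- function(w, suffix) {
  s <- strsplit(suffix, "", fixed = TRUE)[[1L]]
  n <- length(w)
  k <- length(s)
  n >= k && all(w[(n - k + 1L):n] == s)
}

pt_chop <- function(w, k) {
  if (k >= length(w)) character(0) else w[seq_len(length(w) - k)]
}

pt_step1a <- function(w) {
  if (pt_ends(w, "sses")) return(pt_chop(w, 2L))
  if (pt_ends(w, "ies"))  return(pt_chop(w, 2L))
  if (pt_ends(w, "ss"))   return(w)
  if (pt_ends(w, "s"))    return(pt_chop(w, 1L))
  w
}

pt_step1b <- function(w) {
  if (pt_ends(w, "eed")) {
    if (pt_measure(pt_chop(w, 3L)) > 0L) w <- pt_chop(w, 1L)
    return(w)
  }
  stripped <- FALSE
  if (pt_ends(w, "ed") && pt_has_vowel(pt_chop(w, 2L))) {
    w <- pt_chop(w, 2L)
    stripped <- TRUE
  } else if (pt_ends(w, "ing") && pt_has_vowel(pt_chop(w, 3L))) {
    w <- pt_chop(w, 3L)
    stripped <- TRUE
  }
  if (stripped) {
    if (pt_ends(w, "at") || pt_ends(w, "bl") || pt_ends(w, "iz")) {
      w <- c(w, "e")
    } else if (pt_double_cons(w) && !(w[length(w)] %in% c("l", "s", "z"))) {
      w <- pt_chop(w, 1L)
    } else if (pt_measure(w) == 1L && pt_cvc(w)) {
      w <- c(w, "e")
    }
  }
  w
}

pt_step1c <- function(w) {
  if (pt_ends(w, "y") && pt_has_vowel(pt_chop(w, 1L))) {
    w[length(w)] <- "i"
  }
  w
}

# Each entry: suffix -> replacement, applied when the remaining stem has
# m > 0 (steps 2 and 3) or m > 1 (step 4).  Longest matching suffix wins;
# once a suffix matches, no further rule in the step is tried.
pt_rules2 <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
  c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
  c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
  c("ation", "ate"), c("ator", "ate"), c("alism", "al"),
  c("iveness", "ive"), c("fulness", "ful"), c("ousness", "ous"),
  c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
)

pt_rules3 <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

pt_rules4 <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
  "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

pt_apply_rules <- function(w, rules, min_m) {
  lens <- vapply(rules, function(r) nchar(r[[1L]]), integer(1))
  for (i in order(-lens)) {
    suf <- rules[[i]][[1L]]
    if (pt_ends(w, suf)) {
      stem <- pt_chop(w, nchar(suf))
      if (pt_measure(stem) > min_m) {
        rep <- rules[[i]][[2L]]
        if (nzchar(rep)) stem <- c(stem, strsplit(rep, "")[[1L]])
        return(stem)
      }
      return(w)  # suffix matched but condition failed: step is over
    }
  }
  w
}

pt_step2 <- function(w) pt_apply_rules(w, pt_rules2, 0L)
pt_step3 <- function(w) pt_apply_rules(w, pt_rules3, 0L)

pt_step4 <- function(w) {
  lens <- nchar(pt_rules4)
  for (i in order(-lens)) {
    suf <- pt_rules4[i]
    if (pt_ends(w, suf)) {
      stem <- pt_chop(w, nchar(suf))
      if (suf == "ion" &&
          !(length(stem) > 0L && stem[length(stem)] %in% c("s", "t"))) {
        next  # "ion" only counts as a match after s or t
      }
      if (pt_measure(stem) > 1L) return(stem)
      return(w)
    }
  }
  w
}

pt_step5 <- function(w) {
  # 5a
  if (pt_ends(w, "e")) {
    stem <- pt_chop(w, 1L)
    m <- pt_measure(stem)
    if (m > 1L || (m == 1L && !pt_cvc(stem))) w <- stem
  }
  # 5b
  if (pt_measure(w) > 1L && pt_double_cons(w) && w[length(w)] == "l") {
    w <- pt_chop(w, 1L)
  }
  w
}
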
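#' Tokenise a word-report response
#'
#' Lower-cases, strips punctuation (word-internal apostrophes are retained)
#' and splits on whitespace.
#'
#' @param text character scalar.
#' @return character vector of tokens (empty for empty input).
#' @examples
#' normalize_tokens("The cat.")   # "the" "cat"
#' normalize_tokens("it's")       # "it's"
#' @export
normalize_tokens <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  x <- tolower(text)
  x <- gsub("[^a-z0-9']+", " ", x)
  tokens <- strsplit(trimws(x), "\\s+")[[1]]
  tokens <- gsub("^'+|'+$", "", tokens)
  tokens[nzchar(tokens)]
}

#' Score a word report against its target sentence
#'
#' Implements order-sensitive scoring: a reported word counts as correct only
#' if it matches a target word exactly (morphological variants do not match)
#' and appears in the same relative order as in the target; skipped or wrong
#' words in between are allowed, but words reported out of order do not
#' count. This rule is the longest common subsequence (LCS) between target
#' and response — the unique maximal order-preserving matching. Each target
#' token can be matched at most once. An optional homophone map extends token
#' equality: two tokens are equivalent when the map sends them to the same
#' value.
#'
#' @param target character vector of target tokens (non-empty).
#' @param response character vector of reported tokens.
#' @param homophones optional named character vector mapping tokens to
#'   equivalence-class labels (e.g. `c(there = "their/there", their =
#'   "their/there")`). Default empty: exact match only.
#' @return list of class `report_score`: `n_correct`, `n_total`,
#'   `matched_positions` (two-column matrix of target/response indices,
#'   both strictly increasing).
#' @examples
#' tgt <- normalize_tokens("the pitch of the note was high")
#' score_report(tgt, normalize_tokens("the note was high"))$n_correct  # 4
#' @export
score_report <- function(target, response, homophones = NULL) {
  if (length(target) == 0L) stop("target must be non-empty", call. = FALSE)
  canon <- function(tok) {
    if (is.null(homophones)) return(tok)
    mapped <- homophones[tok]
    ifelse(is.na(mapped), tok, mapped)
  }
  a <- canon(target)
  b <- canon(response)
  n <- length(a)
  m <- length(b)
  # classic O(nm) dynamic programme with backtrack for matched positions
  L <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      L[i + 1L, j + 1L] <- if (a[i] == b[j]) {
        L[i, j] + 1L
      } else {
        max(L[i, j + 1L], L[i + 1L, j])
      }
    }
  }
  pairs <- matrix(integer(), ncol = 2L,
                  dimnames = list(NULL, c("target", "response")))
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (a[i] == b[j] && L[i + 1L, j + 1L] == L[i, j] + 1L) {
      pairs <- rbind(c(i, j), pairs)
      i <- i - 1L; j <- j - 1L
    } else if (L[i, j + 1L] >= L[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  structure(list(n_correct = L[n + 1L, m + 1L], n_total = n,
                 matched_positions = pairs),
            class = "report_score")
}

#' @export
print.report_score <- function(x, ...) {
  cat("<report_score>", x$n_correct, "/", x$n_total, "words correct\n")
  invisible(x)
}

#' Score a table of word reports
#'
#' @param reports data.frame with columns `target_text` and `response_text`.
#' @param homophones optional homophone map passed to [score_report()].
#' @return the input with `n_correct`, `n_total` and `proportion` appended.
#' @export
score_report_table <- function(reports, homophones = NULL) {
  stopifnot(all(c("target_text", "response_text") %in% names(reports)))
  scores <- lapply(seq_len(nrow(reports)), function(i) {
    score_report(normalize_tokens(reports$target_text[i]),
                 normalize_tokens(reports$response_text[i]),
                 homophones = homophones)
  })
  reports$n_correct <- vapply(scores, `[[`, integer(1), "n_correct")
  reports$n_total <- vapply(scores, `[[`, integer(1), "n_total")
  reports$proportion <- reports$n_correct / reports$n_total
  reports
}
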
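# Splice-safe encoding design by silent mutation.
#
# Seeded stochastic hill-climbing: start from a random synonymous
# encoding; at each step, try replacing the codon of each residue
# overlapped by the currently offending windows and accept the
# replacement that best lowers the objective (constraint violations,
# then the number of windows at or above threshold, then the maximum
# window score), restarting from a fresh random encoding when stuck.
# The returned encoding is always re-verified through the scanner, so
# soundness does not depend on the search path.

# enumerate every canonical window of one encoding under a flank policy,
# returning kind, score, and the residue indices the window overlaps
.enumerate_windows_one <- function(codes, model, flank_policy = "internal_only",
                                   flanks = NULL) {
  m <- length(codes)
  out <- list()
  for (kind in c("donor", "acceptor")) {
    geom <- splice_geometry(kind)
    W <- geom$width
    pad <- if (flank_policy == "internal_only") c(left = 0L, right = 0L)
           else .flank_pad(geom)
    if (flank_policy == "fixed_flanks") {
      if (is.null(flanks) || length(flanks) != 2L)
        stop("fixed_flanks requires flanks = c(left, right)")
      lf <- .normalize_windows(flanks[1]); rf <- .normalize_windows(flanks[2])
      if (nchar(lf) < pad["left"] || nchar(rf) < pad["right"])
        stop(sprintf("fixed flanks must provide >= %d left and >= %d right bases",
                     pad["left"], pad["right"]))
      ext <- c(.base_codes(substr(lf, nchar(lf) - pad["left"] + 1L, nchar(lf))),
               codes,
               .base_codes(substr(rf, 1L, pad["right"])))
    } else {
      ext <- c(rep(5L, pad["left"]), codes, rep(5L, pad["right"]))
    }
    if (length(ext) < W) next
    d1 <- match(geom$dinucleotide[1], .BASES)
    d2 <- match(geom$dinucleotide[2], .BASES)
    for (o in seq_len(length(ext) - W + 1L)) {
      if (ext[o + geom$obligate[1] - 1L] != d1 ||
          ext[o + geom$obligate[2] - 1L] != d2) next
      win <- ext[o:(o + W - 1L)]
      sc <- if (any(win == 5L)) {
        if (is.null(model$order1))
          stop("flank policy expand_N requires a model with per-position tables")
        sum(model$order1[[kind]][cbind(win, seq_len(W))])
      } else {
        .score_codes(matrix(win, nrow = 1L), kind, model)
      }
      span <- (o - pad[["left"]]):(o - pad[["left"]] + W - 1L)
      span <- span[span >= 1L & span <= m]
      out[[length(out) + 1L]] <- list(kind = kind, score = sc,
                                      residues = unique((span - 1L) %/% 3L + 1L))
    }
  }
  out
}

.constraint_violations <- function(encoding, forbidden, gc_bounds) {
  v <- 0L
  if (length(forbidden)) {
    for (p in forbidden) {
      hits <- gregexpr(p, encoding, fixed = TRUE)[[1]]
      v <- v + sum(hits > 0L)
    }
  }
  if (!is.null(gc_bounds)) {
    gc <- lengths(regmatches(encoding, gregexpr("[GC]", encoding))) /
      nchar(encoding)
    if (gc < gc_bounds[1] || gc > gc_bounds[2]) v <- v + 1L
  }
  as.integer(v)
}

# objective: lexicographic (constraint violations, windows >= tau,
# maximum window score)
.objective <- function(codes, encoding, model, tau, flank_policy, flanks,
                       forbidden, gc_bounds) {
  wins <- .enumerate_windows_one(codes, model, flank_policy, flanks)
  scores <- vapply(wins, `[[`, numeric(1), "score")
  mx <- if (length(scores)) max(scores) else -Inf
  list(violations = .constraint_violations(encoding, forbidden, gc_bounds),
       n_offending = sum(scores >= tau),
       max_score = mx, windows = wins)
}

.obj_better <- function(a, b) {
  if (a$violations != b$violations) return(a$violations < b$violations)
  if (a$n_offending != b$n_offending) return(a$n_offending < b$n_offending)
  a$max_score < b$max_score
}

.codes_to_string <- function(codes) {
  paste(c("A", "C", "G", "T", "N")[codes], collapse = "")
}

#' Design a splice-safe synonymous encoding
#'
#' Searches the synonymous codon space of `pep` for an encoding with no
#' canonical donor or acceptor window scoring `tau` or above under the
#' given flank policy, optionally avoiding forbidden motifs and
#' respecting GC-content bounds. This operationalizes the silent-mutation
#' rescue: removing every window with score at or above 0 removes the
#' predicted splice signals while leaving the protein unchanged.
#'
#' The search is seeded stochastic hill-climbing with restarts; on
#' success the result is independently re-verified with
#' [verify_encoding()]. If no safe encoding is found within the budget,
#' an error of class `spliceaudit_infeasible` is signaled carrying the
#' best encoding found (`best_encoding`) and its maximum window score
#' (`best_max_score`); infeasibility is reported, never silently
#' approximated.
#'
#' @inheritParams risk_profile
#' @param forbidden Character vector of literal motifs the encoding must
#'   not contain (e.g. `c("GGTACC", "GCTAGC", "AATAAA", "ATTAAA")`);
#'   empty by default.
#' @param gc_bounds Optional `c(min, max)` GC fraction bounds.
#' @param max_iter Hill-climbing moves per restart.
#' @param max_restarts Number of random restarts before giving up.
#' @return A `safe_encoding` object with fields `peptide`, `encoding`,
#'   `max_donor`, `max_acceptor`, `tau`, `flank_policy`, `constraints`,
#'   and `trace` (iterations, restarts, seed).
#' @examples
#' m <- load_splice_model()
#' design_safe_encoding("HHHHHH", m, seed = 1)$encoding
#' @export
design_safe_encoding <- function(pep, model = load_splice_model(),
                                 table = codon_table(), tau = 0,
                                 flank_policy = c("internal_only",
                                                  "expand_N",
                                                  "fixed_flanks"),
                                 flanks = NULL, forbidden = character(),
                                 gc_bounds = NULL, seed = NULL,
                                 max_iter = 200L, max_restarts = 50L) {
  pep <- as_peptide(pep)
  flank_policy <- match.arg(flank_policy)
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (is.null(seed)) stop("design_safe_encoding requires a seed")
  stopifnot(max_restarts >= 1L, max_iter >= 1L)
  codons <- .residue_codons(pep, table)
  codon_codes <- lapply(codons, function(cc) .code_matrix(cc, 3L))
  L <- length(codons)
  set.seed(seed)
  best_overall <- NULL
  total_iter <- 0L

  for (restart in seq_len(max_restarts)) {
    pick <- vapply(codons, function(cc) sample.int(length(cc), 1L), integer(1))
    codes <- unlist(lapply(seq_len(L), function(i) codon_codes[[i]][pick[i], ]))
    enc <- .codes_to_string(codes)
    obj <- .objective(codes, enc, model, tau, flank_policy, flanks,
                      forbidden, gc_bounds)
    for (iter in seq_len(max_iter)) {
      total_iter <- total_iter + 1L
      if (obj$violations == 0L && obj$n_offending == 0L) break
      # residues touched by any offending window (or, if the trouble is
      # a motif/GC constraint, any residue)
      off <- Filter(function(w) w$score >= tau, obj$windows)
      target_res <- if (length(off)) {
        sort(unique(unlist(lapply(off, `[[`, "residues"))))
      } else seq_len(L)
      best_move <- NULL
      for (i in target_res) {
        for (j in seq_along(codons[[i]])) {
          if (j == pick[i]) next
          cand <- codes
          cand[(3L * i - 2L):(3L * i)] <- codon_codes[[i]][j, ]
          cand_enc <- .codes_to_string(cand)
          cand_obj <- .objective(cand, cand_enc, model, tau, flank_policy,
                                 flanks, forbidden, gc_bounds)
          if (is.null(best_move) || .obj_better(cand_obj, best_move$obj)) {
            best_move <- list(i = i, j = j, codes = cand, enc = cand_enc,
                              obj = cand_obj)
          }
        }
      }
      if (is.null(best_move) || !.obj_better(best_move$obj, obj)) break
      pick[best_move$i] <- best_move$j
      codes <- best_move$codes
      enc <- best_move$enc
      obj <- best_move$obj
    }
    if (is.null(best_overall) || .obj_better(obj, best_overall$obj)) {
      best_overall <- list(enc = enc, obj = obj)
    }
    if (obj$violations == 0L && obj$n_offending == 0L) {
      verdict <- verify_encoding(enc, pep, model, tau, flank_policy, flanks)
      if (verdict$verdict != "safe") {
        stop("internal error: designed encoding failed independent verification")
      }
      cm <- matrix(codes, nrow = 1L)
      return(structure(list(
        peptide = pep, encoding = enc,
        max_donor = unname(.max_window_scores(cm, "donor", model,
                                              flank_policy, flanks)),
        max_acceptor = unname(.max_window_scores(cm, "acceptor", model,
                                                 flank_policy, flanks)),
        tau = tau, flank_policy = flank_policy,
        constraints = list(forbidden = forbidden, gc_bounds = gc_bounds),
        trace = list(iterations = total_iter, restarts = restart,
                     seed = seed),
        model_checksum = model$checksum), class = "safe_encoding"))
    }
  }
  stop(structure(
    class = c("spliceaudit_infeasible", "error", "condition"),
    list(message = sprintf(
      "no safe encoding of %s found within %d restarts (best max score %.2f bits, %d constraint violations)",
      pep$residues, max_restarts, best_overall$obj$max_score,
      best_overall$obj$violations),
      call = NULL,
      best_encoding = best_overall$enc,
      best_max_score = best_overall$obj$max_score)))
}

#' @export
print.safe_encoding <- function(x, ...) {
  cat(sprintf("<safe_encoding> %s (%s)\n  %s\n", x$peptide$name,
              x$peptide$residues, x$encoding))
  cat(sprintf("  max donor %.2f, max acceptor %.2f (tau=%g, %s; %d iterations, %d restarts)\n",
              ifelse(is.na(x$max_donor), -Inf, x$max_donor),
              ifelse(is.na(x$max_acceptor), -Inf, x$max_acceptor),
              x$tau, x$flank_policy, x$trace$iterations, x$trace$restarts))
  invisible(x)
}

#' Verify that an encoding is splice-safe
#'
#' Independent check decoupled from the search: confirms that the
#' encoding translates to the stated peptide and that no canonical
#' window reaches `tau` under the flank policy. Internal windows are
#' re-found through the scanner ([find_splice_windows()]); boundary
#' windows (non-internal policies) are scored with worst-case or fixed
#' flanking context.
#'
#' @inheritParams design_safe_encoding
#' @param encoding DNA string of length `3 * nchar(peptide)`.
#' @return A list with `verdict` (`"safe"` or `"unsafe"`), `failure`
#'   (`NA`, `"translation_mismatch"`, or `"splice_windows"`), and
#'   `offending` (a data frame of windows scoring at or above `tau`).
#' @export
verify_encoding <- function(encoding, pep, model = load_splice_model(),
                            tau = 0, flank_policy = c("internal_only",
                                                      "expand_N",
                                                      "fixed_flanks"),
                            flanks = NULL) {
  pep <- as_peptide(pep)
  flank_policy <- match.arg(flank_policy)
  encoding <- .normalize_windows(encoding)
  if (nchar(encoding) != 3L * nchar(pep$residues))
    stop(sprintf("encoding length %d does not match 3 x %d residues",
                 nchar(encoding), nchar(pep$residues)))
  if (translate_encoding(encoding) != pep$residues) {
    return(list(verdict = "unsafe", failure = "translation_mismatch",
                offending = NULL))
  }
  windows <- find_splice_windows(nuc_sequence(pep$name, encoding), model,
                                 tau = tau, strands = "+",
                                 require_canonical = TRUE)
  offending <- as.data.frame(windows)
  if (flank_policy != "internal_only") {
    wins <- .enumerate_windows_one(.base_codes(encoding), model,
                                   flank_policy, flanks)
    extra <- Filter(function(w) w$score >= tau, wins)
    if (length(extra) && nrow(offending) == 0L) {
      offending <- data.frame(
        seq = pep$name,
        kind = vapply(extra, `[[`, "", "kind"),
        start = NA_integer_, end = NA_integer_, strand = "+",
        boundary = NA_integer_, window_seq = NA_character_,
        score = vapply(extra, `[[`, numeric(1), "score"))
    }
  }
  if (nrow(offending) > 0L) {
    list(verdict = "unsafe", failure = "splice_windows",
         offending = offending)
  } else {
    list(verdict = "safe", failure = NA_character_, offending = NULL)
  }
}
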
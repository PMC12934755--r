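db_pairs <- function(t) {
  # all pairs with their page; reuses the dot-bracket parser's page stacks
  ch <- strsplit(t, "")[[1L]]
  stacks <- rep(list(integer()), length(PAGE_OPEN))
  out <- NULL
  for (i in seq_along(ch)) {
    pg <- match(ch[[i]], PAGE_OPEN)
    if (!is.na(pg)) stacks[[pg]] <- c(stacks[[pg]], i)
    else {
      pg <- match(ch[[i]], PAGE_CLOSE)
      if (!is.na(pg)) {
        if (length(stacks[[pg]]) == 0L) stop("unbalanced '", ch[[i]],
                                             "' at position ", i)
        j <- stacks[[pg]][[length(stacks[[pg]])]]
        stacks[[pg]] <- stacks[[pg]][-length(stacks[[pg]])]
        out <- rbind(out, c(j, i, pg - 1L))
      } else if (ch[[i]] != ".") {
        stop("invalid dot-bracket character '", ch[[i]], "' at position ", i)
      }
    }
  }
  if (any(vapply(stacks, length, 1L) > 0L)) stop("unbalanced dot-bracket")
  if (is.null(out)) out <- matrix(integer(), ncol = 3L)
  colnames(out) <- c("i", "j", "page")
  out[order(out[, 1L]), , drop = FALSE]
}

#' Locate pseudoknot regions in extended dot-bracket text
#'
#' Each maximal family of square-bracket (page >= 1) pairs connected by
#' interval overlap seeds a span from its first opening to its last closing
#' bracket. While the span contains a bracket whose partner lies outside, the
#' span is extended to include the partner; overlapping spans are then
#' merged. Returns an empty list when no square bracket occurs.
#'
#' @param t balanced extended dot-bracket string
#' @return list of integer `c(start, end)` spans (1-based, inclusive)
#' @export
find_pseudoknots <- function(t) {
  pr <- db_pairs(t)
  knot <- pr[pr[, "page"] >= 1L, , drop = FALSE]
  if (nrow(knot) == 0L) return(list())
  # families: connected components under interval overlap
  ord <- order(knot[, "i"])
  knot <- knot[ord, , drop = FALSE]
  fam <- integer(nrow(knot)); fam[1L] <- 1L
  cur_end <- knot[1L, "j"]
  for (r in seq_len(nrow(knot))[-1L]) {
    if (knot[r, "i"] <= cur_end) {
      fam[r] <- fam[r - 1L]
      cur_end <- max(cur_end, knot[r, "j"])
    } else {
      fam[r] <- fam[r - 1L] + 1L
      cur_end <- knot[r, "j"]
    }
  }
  partner <- rep(NA_integer_, nchar(t))
  partner[pr[, "i"]] <- pr[, "j"]
  partner[pr[, "j"]] <- pr[, "i"]
  spans <- lapply(unique(fam), function(f) {
    s <- min(knot[fam == f, "i"]); e <- max(knot[fam == f, "j"])
    repeat {
      inside <- s:e
      out <- partner[inside]
      out <- out[!is.na(out)]
      if (length(out) == 0L || (min(out) >= s && max(out) <= e)) break
      s <- min(s, out); e <- max(e, out)
    }
    c(s, e)
  })
  # merge overlapping spans
  spans <- spans[order(vapply(spans, `[[`, 1L, 1L))]
  merged <- list(spans[[1L]])
  for (sp in spans[-1L]) {
    last <- merged[[length(merged)]]
    if (sp[[1L]] <= last[[2L]]) {
      merged[[length(merged)]] <- c(last[[1L]], max(last[[2L]], sp[[2L]]))
    } else merged[[length(merged) + 1L]] <- sp
  }
  merged
}

# page-0 pair tree helpers ---------------------------------------------------

p0_children <- function(p0, i, j) {
  # direct page-0 child pairs of (i, j)
  inside <- p0[p0[, "i"] > i & p0[, "j"] < j, , drop = FALSE]
  if (nrow(inside) == 0L) return(inside)
  keep <- vapply(seq_len(nrow(inside)), function(r) {
    !any(inside[, "i"] < inside[r, "i"] & inside[, "j"] > inside[r, "j"])
  }, logical(1))
  inside[keep, , drop = FALSE]
}

p0_innermost_containing <- function(p0, pos) {
  cand <- p0[p0[, "i"] < pos & p0[, "j"] > pos, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  r <- which.min(cand[, "j"] - cand[, "i"])
  cand[r, c("i", "j")]
}

p0_is_simple_hairpin <- function(p0, i, j) {
  # subtree is a plain helix (with bulges/internal loops) ending in a
  # hairpin loop: every descendant closes at most one child
  repeat {
    ch <- p0_children(p0, i, j)
    if (nrow(ch) == 0L) return(TRUE)
    if (nrow(ch) > 1L) return(FALSE)
    i <- ch[1L, "i"]; j <- ch[1L, "j"]
  }
}

p0_helix_outer <- function(p0, i, j) {
  # outermost pair of the helix stack containing (i, j): walk parents while
  # the parent closes only this child
  repeat {
    parent <- NULL
    cand <- p0[p0[, "i"] < i & p0[, "j"] > j, , drop = FALSE]
    if (nrow(cand) > 0L) {
      r <- which.min(cand[, "j"] - cand[, "i"])
      pi <- cand[r, "i"]; pj <- cand[r, "j"]
      if (nrow(p0_children(p0, pi, pj)) == 1L) parent <- c(pi, pj)
    }
    if (is.null(parent)) return(c(i, j))
    i <- parent[[1L]]; j <- parent[[2L]]
  }
}

group_context <- function(p0, group) {
  cont <- lapply(group, function(pos) p0_innermost_containing(p0, pos))
  if (all(vapply(cont, is.null, logical(1)))) {
    return(list(ctx = "SS", pair = NULL))
  }
  if (any(vapply(cont, is.null, logical(1)))) {
    return(list(ctx = "MIXED", pair = NULL))
  }
  m <- unique(do.call(rbind, cont))
  if (nrow(m) > 1L) return(list(ctx = "MIXED", pair = NULL))
  i <- m[1L, 1L]; j <- m[1L, 2L]
  ch <- p0_children(p0, i, j)
  if (nrow(ch) == 0L) return(list(ctx = "HAIRPIN", pair = c(i, j)))
  simple <- vapply(seq_len(nrow(ch)), function(r) {
    p0_is_simple_hairpin(p0, ch[r, "i"], ch[r, "j"])
  }, logical(1))
  if (all(simple)) list(ctx = "HP_PLUS", pair = c(i, j))
  else list(ctx = "LOOP", pair = c(i, j))
}

#' Classify one pseudoknot region into six topological types
#'
#' Deterministic cascade over the pairing topology of the span (most specific
#' first, long-range `LR` strictly the fallback):
#' `HHH` (kissing hairpin) when both crossing-pair endpoint groups lie in
#' hairpin loops of two distinct stems; `HLIN` when one group lies in a
#' hairpin loop decorated with inserted simple hairpin element(s) and the
#' other is single-stranded; `HLOUT` when the plain H geometry holds and at
#' least one extra hairpin sits in the single-stranded segment between the
#' pseudoknot stem and the far group; `LL` when an endpoint group lies in a
#' non-hairpin loop (internal/bulge/junction context); `H` for the plain
#' hairpin-loop-to-single-strand geometry; `LR` otherwise (including spans
#' with a third crossing family or mixed endpoint contexts).
#'
#' @param span integer `c(start, end)` from [find_pseudoknots()]
#' @param t the full extended dot-bracket string the span refers to
#' @return one of `"HHH"`, `"HLIN"`, `"HLOUT"`, `"LL"`, `"H"`, `"LR"`
#' @export
classify_pseudoknot <- function(span, t) {
  pr <- db_pairs(t)
  s <- span[[1L]]; e <- span[[2L]]
  inside <- pr[pr[, "i"] >= s & pr[, "j"] <= e, , drop = FALSE]
  knot <- inside[inside[, "page"] == 1L, , drop = FALSE]
  if (nrow(knot) == 0L) stop("span contains no crossing (page-1) pairs")
  if (any(inside[, "page"] >= 2L)) return("LR")
  p0 <- inside[inside[, "page"] == 0L, , drop = FALSE]
  gl <- sort(knot[, "i"]); gr <- sort(knot[, "j"])
  cl <- group_context(p0, gl)
  cr <- group_context(p0, gr)
  ctx <- c(cl$ctx, cr$ctx)
  if (all(ctx == "HAIRPIN") && !identical(cl$pair, cr$pair)) return("HHH")
  hp_plus_ss <- (cl$ctx == "HP_PLUS" && cr$ctx == "SS") ||
    (cr$ctx == "HP_PLUS" && cl$ctx == "SS")
  if (hp_plus_ss) return("HLIN")
  h_geom <- (cl$ctx == "HAIRPIN" && cr$ctx == "SS") ||
    (cr$ctx == "HAIRPIN" && cl$ctx == "SS")
  if (h_geom) {
    hp <- if (cl$ctx == "HAIRPIN") cl else cr
    ss_group <- if (cl$ctx == "HAIRPIN") gr else gl
    outer <- p0_helix_outer(p0, hp$pair[[1L]], hp$pair[[2L]])
    seg <- if (min(ss_group) > outer[[2L]]) {
      c(outer[[2L]], min(ss_group))
    } else {
      c(max(ss_group), outer[[1L]])
    }
    extra <- p0[p0[, "i"] > seg[[1L]] & p0[, "j"] < seg[[2L]], , drop = FALSE]
    has_hairpin <- FALSE
    for (r in seq_len(nrow(extra))) {
      if (nrow(p0_children(p0, extra[r, "i"], extra[r, "j"])) == 0L) {
        has_hairpin <- TRUE; break
      }
    }
    if (has_hairpin) return("HLOUT")
  }
  if (any(ctx %in% c("HP_PLUS", "LOOP"))) return("LL")
  if (h_geom) return("H")
  "LR"
}

#' Pseudoknot inventory of a structure graph
#'
#' Drops non-WC edges, converts to extended dot-bracket, locates crossing
#' regions and classifies each. One record per merged region.
#'
#' @param g an `rna_graph`
#' @return list of records with fields `span` (start, end), `dot_bracket`
#'   (text over the span), `pk_class`, `members` (residue keys in the span)
#' @export
pseudoknot_inventory <- function(g) {
  t <- to_dot_bracket(g)
  spans <- find_pseudoknots(t)
  lapply(spans, function(sp) {
    structure(
      list(span = sp,
           dot_bracket = substr(t, sp[[1L]], sp[[2L]]),
           pk_class = classify_pseudoknot(sp, t),
           members = g$nodes$key[sp[[1L]]:sp[[2L]]]),
      class = "pseudoknot_record")
  })
}

#' @export
print.pseudoknot_record <- function(x, ...) {
  cat(sprintf("pseudoknot [%d,%d] class %s: %s\n", x$span[[1L]], x$span[[2L]],
              x$pk_class, x$dot_bracket))
  invisible(x)
}
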
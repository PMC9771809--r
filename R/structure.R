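# Secondary-structure handling: dot-bracket parsing, bpRNA-style loop-type
# annotation, structure-graph distances and unpaired probabilities.

BRACKET_PAIRS <- list(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"))

#' Parse a dot-bracket secondary structure into a pair table
#'
#' Converts a dot-bracket string into a pair table: for every position, the
#' index of its base-pairing partner (or `NA` when unpaired). Plain
#' parentheses encode nested pairs; with `allow_pseudoknots = TRUE` the extra
#' bracket alphabets `[]`, `{}` and `<>` are parsed as additional (possibly
#' crossing) pair layers.
#'
#' Positions are 1-based throughout the R API.
#'
#' @param db Dot-bracket string, e.g. `"((..))"`.
#' @param allow_pseudoknots Parse `[]`, `{}` and `<>` as pairs as well
#'   (default `FALSE`: those characters are rejected).
#' @return An object of class `pair_table`: a list with elements `length`
#'   (integer) and `partner` (integer vector, `NA` = unpaired).
#' @examples
#' pt <- parse_dotbracket("(.((...)))")
#' pt$partner
#' @export
parse_dotbracket <- function(db, allow_pseudoknots = FALSE) {
  stopifnot(is.character(db), length(db) == 1L)
  cc <- chars(db)
  n <- length(cc)
  alphabets <- if (allow_pseudoknots) BRACKET_PAIRS else BRACKET_PAIRS[1]
  open_chars <- vapply(alphabets, `[`, "", 1L)
  close_chars <- vapply(alphabets, `[`, "", 2L)
  legal <- c(".", unlist(alphabets))
  bad <- which(!cc %in% legal)
  if (length(bad)) {
    stop(sprintf("illegal character '%s' at position %d of dot-bracket string",
                 cc[bad[1]], bad[1]), call. = FALSE)
  }
  partner <- rep(NA_integer_, n)
  stacks <- rep(list(integer()), length(alphabets))
  for (i in seq_len(n)) {
    a <- match(cc[i], open_chars)
    if (!is.na(a)) {
      stacks[[a]] <- c(stacks[[a]], i)
      next
    }
    a <- match(cc[i], close_chars)
    if (!is.na(a)) {
      if (!length(stacks[[a]])) {
        stop(sprintf("unbalanced bracket: unmatched '%s' at position %d",
                     cc[i], i), call. = FALSE)
      }
      j <- stacks[[a]][length(stacks[[a]])]
      stacks[[a]] <- stacks[[a]][-length(stacks[[a]])]
      partner[i] <- j
      partner[j] <- i
    }
  }
  leftover <- unlist(stacks)
  if (length(leftover)) {
    stop(sprintf("unbalanced bracket: unmatched '%s' at position %d",
                 cc[min(leftover)], min(leftover)), call. = FALSE)
  }
  structure(list(length = n, partner = partner), class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("pair table: %d nt, %d base pairs\n",
              x$length, sum(!is.na(x$partner)) %/% 2L))
  invisible(x)
}

as_pair_table <- function(x, ...) {
  if (inherits(x, "pair_table")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_dotbracket(x, ...))
  stop("expected a pair_table or a dot-bracket string", call. = FALSE)
}

# Validate the pair-table invariants (involution, no self pairs).
validate_pair_table <- function(pt) {
  p <- pt$partner
  paired <- which(!is.na(p))
  if (any(p[paired] == paired)) stop("position paired with itself", call. = FALSE)
  if (any(p[p[paired]] != paired)) stop("partner is not an involution", call. = FALSE)
  invisible(pt)
}

# Loop-structure bookkeeping used by both the annotator and motif aggregation.
# Returns, per position: the loop class over {S,H,I,B,M,X,E}; for hairpin
# positions the hairpin-loop length; for internal-loop positions whether the
# loop's two unpaired sides have equal length.
.annotate_details <- function(pt) {
  p <- pt$partner
  n <- pt$length
  cls <- rep(NA_character_, n)
  cls[!is.na(p)] <- "S"
  hairpin_len <- rep(NA_integer_, n)
  internal_sym <- rep(NA, n)

  # enclosing[i]: opening index of the innermost pair enclosing i (0 = exterior);
  # children[[as.character(t)]]: opening indices of pairs directly inside pair t.
  enclosing <- integer(n)
  children <- new.env(parent = emptyenv())
  stack <- integer()
  for (i in seq_len(n)) {
    top <- if (length(stack)) stack[length(stack)] else 0L
    if (!is.na(p[i]) && p[i] > i) {          # opening a pair
      key <- as.character(top)
      kids <- if (!is.null(children[[key]])) children[[key]] else integer()
      children[[key]] <- c(kids, i)
      enclosing[i] <- top
      stack <- c(stack, i)
    } else if (!is.na(p[i]) && p[i] < i) {   # closing a pair
      stack <- stack[-length(stack)]
      enclosing[i] <- if (length(stack)) stack[length(stack)] else 0L
    } else {
      enclosing[i] <- top
    }
  }

  unpaired <- which(is.na(p))
  if (!length(unpaired)) {
    return(list(classes = cls, hairpin_len = hairpin_len,
                internal_sym = internal_sym))
  }
  # maximal runs of consecutive unpaired positions
  run_id <- cumsum(c(1L, diff(unpaired) != 1L))
  for (r in split(unpaired, run_id)) {
    enc <- enclosing[r[1]]
    if (enc == 0L) {
      # exterior: terminus-touching runs are ends, interior exterior runs X
      cls[r] <- if (r[1] == 1L || r[length(r)] == n) "E" else "X"
      next
    }
    q <- p[enc]
    key <- as.character(enc)
    kids <- if (!is.null(children[[key]])) children[[key]] else integer()
    if (length(kids) == 0L) {                 # hairpin loop
      cls[r] <- "H"
      hairpin_len[r] <- q - enc - 1L
    } else if (length(kids) == 1L) {          # internal loop or bulge
      a <- kids[1]; b <- p[a]
      left <- a - enc - 1L
      right <- q - b - 1L
      if (left > 0L && right > 0L) {
        cls[r] <- "I"
        internal_sym[r] <- left == right
      } else {
        cls[r] <- "B"
      }
    } else {                                  # >= 2 branches: multiloop
      cls[r] <- "M"
    }
  }
  list(classes = cls, hairpin_len = hairpin_len, internal_sym = internal_sym)
}

#' Annotate bpRNA-style loop types
#'
#' Assigns every position one of the seven bpRNA structural classes: `S`
#' (stem, i.e. paired), `H` (hairpin loop), `B` (bulge: unpaired run on
#' exactly one side of a single-branch loop), `I` (internal loop: unpaired
#' runs on both sides), `M` (loop enclosed by three or more helix branches),
#' `X` (exterior-region unpaired run flanked by helices on both sides) and
#' `E` (exterior-region unpaired run touching a sequence end).
#'
#' @param pt A `pair_table` or a dot-bracket string.
#' @return A single string of loop-type characters, one per position.
#' @examples
#' annotate_loop_types(".((((...)))).")   # "ESSSSHHHSSSSE"
#' annotate_loop_types("(.((...)))")      # "SBSSHHHSSS"
#' @export
annotate_loop_types <- function(pt) {
  pt <- as_pair_table(pt)
  validate_pair_table(pt)
  paste(.annotate_details(pt)$classes, collapse = "")
}

#' Shortest-path distance matrix on the secondary-structure graph
#'
#' Builds the graph whose nodes are nucleotides and whose edges are the
#' backbone links (i, i+1) plus one edge per base pair, then computes
#' all-pairs shortest-path hop counts. This is the distance embedding widely
#' used to encode nucleotide proximity in structured RNAs: paired positions
#' that are far apart in sequence become close in the graph.
#'
#' @param pt A `pair_table` or dot-bracket string.
#' @return An object of class `structure_graph`: list with `length`, `edges`
#'   (two-column matrix) and `dist` (dense symmetric integer matrix of hop
#'   counts).
#' @export
graph_distance_matrix <- function(pt) {
  pt <- as_pair_table(pt)
  validate_pair_table(pt)
  n <- pt$length
  p <- pt$partner
  backbone <- if (n > 1L) cbind(seq_len(n - 1L), 2:n) else
    matrix(integer(), ncol = 2)
  pairs_i <- which(!is.na(p) & p > seq_len(n))
  pair_edges <- cbind(pairs_i, p[pairs_i])
  edges <- rbind(backbone, pair_edges)
  g <- igraph::make_graph(as.vector(t(edges)), n = n, directed = FALSE)
  d <- igraph::distances(g)
  dimnames(d) <- NULL
  structure(list(length = n, edges = edges, dist = d),
            class = "structure_graph")
}

#' @export
print.structure_graph <- function(x, ...) {
  cat(sprintf("structure graph: %d nodes, %d edges\n", x$length, nrow(x$edges)))
  invisible(x)
}

#' Per-position unpaired probability from a base-pair probability matrix
#'
#' Given a symmetric base-pair probability (bpp) matrix, the probability of
#' position i being unpaired is one minus the total pairing mass in its row,
#' clipped to `[0, 1]`.
#'
#' @param bpp Square numeric matrix; `bpp[i, j]` is the probability that i
#'   pairs with j. Must be symmetric with row sums at most 1 (within
#'   `tolerance`).
#' @param tolerance Slack allowed on symmetry, entry range and row sums.
#' @return Numeric vector of unpaired probabilities.
#' @export
unpaired_probability <- function(bpp, tolerance = 1e-6) {
  if (!is.matrix(bpp) || nrow(bpp) != ncol(bpp)) {
    stop("bpp must be a square matrix", call. = FALSE)
  }
  if (any(abs(bpp - t(bpp)) > tolerance)) {
    stop("bpp matrix is not symmetric", call. = FALSE)
  }
  if (any(bpp < -tolerance) || any(bpp > 1 + tolerance)) {
    stop("bpp entries must lie in [0, 1]", call. = FALSE)
  }
  rs <- rowSums(bpp)
  if (any(rs > 1 + tolerance)) {
    stop(sprintf("bpp row sum exceeds 1 (max %.6f)", max(rs)), call. = FALSE)
  }
  pmin(pmax(1 - rs, 0), 1)
}
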
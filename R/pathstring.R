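# State-sequence representation of a transition pathway.
#
# Internally a pathway string is an integer vector of state ids (small
# non-negative integers).  For display and plain-text round-tripping the ids
# are mapped bijectively onto a 94-symbol printable alphabet; ids beyond the
# alphabet spill into higher Unicode code points so per-symbol operations
# remain correct for arbitrarily many states.

.ps_alphabet_chars <- strsplit(
  paste0("0123456789",
         "ABCDEFGHIJKLMNOPQRSTUVWXYZ",
         "abcdefghijklmnopqrstuvwxyz",
         "!\"#$%&'()*+,-./:;<=>?@[\\]^_`{|}~"),
  "")[[1]]

#' Display alphabet for state ids
#'
#' Returns the 94 printable characters used to render state ids 0..93; state
#' ids of 94 or more are rendered as Unicode code points starting at U+0100.
#'
#' @return Character vector of length 94.
#' @export
ps_alphabet <- function() .ps_alphabet_chars

#' Encode state ids as a display string
#'
#' @param symbols Integer vector of non-negative state ids.
#' @return A single character string, one display character per state id.
#' @seealso [decode_symbols()]
#' @export
encode_symbols <- function(symbols) {
  symbols <- as.integer(symbols)
  if (length(symbols) == 0) return("")
  if (any(symbols < 0)) stop("state ids must be non-negative for encoding")
  codes <- ifelse(symbols < 94L,
                  utf8ToInt(paste(.ps_alphabet_chars, collapse = ""))[symbols + 1L],
                  0x100L + symbols - 94L)
  intToUtf8(codes)
}

#' Decode a display string back to state ids
#'
#' @param string A character string produced by [encode_symbols()].
#' @return Integer vector of state ids.
#' @export
decode_symbols <- function(string) {
  if (nchar(string) == 0) return(integer(0))
  cps <- utf8ToInt(string)
  base <- utf8ToInt(paste(.ps_alphabet_chars, collapse = ""))
  out <- integer(length(cps))
  for (i in seq_along(cps)) {
    if (cps[i] >= 0x100L) {
      out[i] <- cps[i] - 0x100L + 94L
    } else {
      m <- match(cps[i], base)
      if (is.na(m)) stop("character not in the display alphabet: ",
                         intToUtf8(cps[i]))
      out[i] <- m - 1L
    }
  }
  out
}

# Coerce any accepted pathway representation to an integer symbol vector.
as_symbols <- function(x) {
  if (inherits(x, "pathway")) return(x$symbols)
  if (inherits(x, "path_string")) return(unclass(x)$symbols)
  if (is.character(x)) {
    if (length(x) != 1) stop("expected a single string")
    return(decode_symbols(x))
  }
  if (is.numeric(x)) return(as.integer(x))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a pathway string")
}

#' Construct a pathway string
#'
#' A `path_string` is an ordered sequence of visited state ids, the basic
#' object scored by [gestalt_similarity()].
#'
#' @param x Integer vector of state ids, or a display-alphabet string.
#' @return An object of class `path_string`.
#' @examples
#' path_string(c(0, 3, 4, 5))
#' path_string("0345")
#' @export
path_string <- function(x) {
  symbols <- as_symbols(x)
  structure(list(symbols = symbols), class = "path_string")
}

#' @export
length.path_string <- function(x) length(unclass(x)$symbols)

#' @export
as.character.path_string <- function(x, ...) encode_symbols(unclass(x)$symbols)

#' @export
print.path_string <- function(x, ...) {
  cat("<path_string> ", as.character(x), "  (", length(x), " symbols)\n",
      sep = "")
  invisible(x)
}

#' Construct a pathway record
#'
#' Bundles a state-sequence string with its statistical weight and frame
#' metadata.  Produced by [extract_cmd()] and [extract_we()]; consumed by
#' [pairwise_distances()] and the class-report functions.
#'
#' @param symbols State-id vector (or display string) for the pathway: the
#'   states visited from the first frame after the last source exit up to and
#'   including the first target entry.
#' @param weight Positive statistical weight (uniform `1/n` for conventional
#'   MD, the arriving segment's weight for weighted-ensemble data).
#' @param start_frame,end_frame 0-based global frame indices of the window.
#' @param event_duration_frames Frames from last source exit to first target
#'   entry (the barrier-crossing time in frames).
#' @param origin List identifying the source trajectory/segment.
#' @param id Optional pathway identifier.
#' @return An object of class `pathway`.
#' @export
pathway <- function(symbols, weight = 1, start_frame = NA_integer_,
                    end_frame = NA_integer_,
                    event_duration_frames = NULL, origin = list(), id = NA) {
  symbols <- as_symbols(symbols)
  if (length(symbols) < 1) stop("a pathway must contain at least one symbol")
  if (!is.na(weight) && weight <= 0) stop("pathway weight must be positive")
  if (is.null(event_duration_frames)) {
    event_duration_frames <- if (!is.na(start_frame) && !is.na(end_frame))
      end_frame - start_frame + 1L else length(symbols)
  }
  structure(list(symbols = symbols, weight = weight,
                 start_frame = as.integer(start_frame),
                 end_frame = as.integer(end_frame),
                 event_duration_frames = as.integer(event_duration_frames),
                 origin = origin, id = id),
            class = "pathway")
}

#' @export
print.pathway <- function(x, ...) {
  cat("<pathway> ", encode_symbols(x$symbols),
      "  weight=", format(x$weight, digits = 4),
      "  duration=", x$event_duration_frames, " frames\n", sep = "")
  invisible(x)
}

# Weight accessor tolerant of plain strings (weight 1).
pathway_weight <- function(x) {
  if (inherits(x, "pathway") && !is.na(x$weight)) x$weight else 1
}
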
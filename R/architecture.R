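#' Enhancer architecture: which Runt binding sites a construct carries
#'
#' Constructs are named by a 3-character bit string over the three candidate
#' Runt binding sites of the hunchback P2 scaffold, ordered distal to
#' promoter-proximal: the leftmost bit is site 1 (farthest from the promoter),
#' the rightmost bit is site 3 (promoter-proximal).  `"000"` is the
#' unmodified enhancer, `"111"` carries all three sites.  Every construct
#' carries six Bicoid binding sites.
#'
#' @param construct_id character scalar over `{"0","1"}^3`, e.g. `"011"`.
#' @return An object of class `"enhancer_architecture"` with elements
#'   `construct_id`, `sites` (integer subset of 1:3, 1 = distal) and
#'   `n_bicoid_sites` (always 6).
#' @examples
#' enhancer_architecture("011")$sites  # sites 2 (middle) and 3 (proximal)
#' @export
enhancer_architecture <- function(construct_id) {
  if (!is.character(construct_id) || length(construct_id) != 1L ||
      !grepl("^[01]{3}$", construct_id)) {
    stop("'construct_id' must be a 3-character string over {0,1}, got: ",
         deparse(construct_id))
  }
  bits <- as.integer(strsplit(construct_id, "")[[1L]])
  structure(
    list(construct_id = construct_id,
         sites = which(bits == 1L),
         n_bicoid_sites = 6L),
    class = "enhancer_architecture"
  )
}

#' @export
print.enhancer_architecture <- function(x, ...) {
  labels <- c("distal", "middle", "proximal")
  cat("Enhancer architecture [", x$construct_id, "]: ",
      length(x$sites), " Runt site(s)",
      if (length(x$sites)) paste0(" (", paste(labels[x$sites], collapse = ", "), ")"),
      ", ", x$n_bicoid_sites, " Bicoid sites\n", sep = "")
  invisible(x)
}

#' All eight construct identifiers in canonical order
#'
#' Canonical order is by number of Runt sites, then lexicographic, matching
#' the order in which the inference cascade consumes the constructs.
#' @return character vector of length 8.
#' @export
all_construct_ids <- function() {
  c("000", "100", "010", "001", "011", "101", "110", "111")
}

## Pair key helpers: unordered site pairs are keyed "12", "13", "23".
pair_key <- function(i, j) paste0(min(i, j), max(i, j))

site_pairs <- function(sites) {
  if (length(sites) < 2L) return(character(0))
  cmb <- utils::combn(sort(sites), 2L)
  apply(cmb, 2L, function(z) pair_key(z[1L], z[2L]))
}

#' Map a two-site construct to its unordered site pair key
#'
#' `"011"` carries sites \{2,3\}, `"101"` carries \{1,3\}, `"110"` carries
#' \{1,2\}; the returned key (e.g. `"23"`) indexes the pairwise cooperativity
#' maps of [repression_params()].
#' @param construct_id a two-site construct bit string.
#' @return character pair key.
#' @export
construct_pair_key <- function(construct_id) {
  arch <- enhancer_architecture(construct_id)
  if (length(arch$sites) != 2L) {
    stop("construct [", construct_id, "] does not carry exactly two Runt sites")
  }
  pair_key(arch$sites[1L], arch$sites[2L])
}
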
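# Silhouette binarization and Freeman chain coding.
#
# Codes follow the 8-direction Freeman convention in mathematical
# coordinates (x = column, y = -row): 0 = +x, 2 = +y, 4 = -x, 6 = -y,
# counterclockwise.

freeman_moves <- rbind(  # dr, dc per code 0..7
  c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
  c(0, -1), c(1, -1), c(1, 0), c(1, 1))

#' Freeman chain code
#'
#' @param start integer `(row, col)` of the start pixel.
#' @param codes integer sequence over 0..7.
#' @return A `chaincode` object (validated: closed, length >= 4).
#' @export
chaincode <- function(start, codes) {
  codes <- as.integer(codes)
  if (length(codes) < 4L) abort("chain code must have length >= 4")
  if (any(codes < 0L | codes > 7L)) abort("chain codes must lie in 0..7")
  disp <- freeman_moves[codes + 1L, , drop = FALSE]
  if (any(colSums(disp) != 0L)) abort("chain code is not closed")
  structure(list(start = as.integer(start), codes = codes),
            class = "chaincode")
}

#' @export
print.chaincode <- function(x, ...) {
  cat(sprintf("<chaincode: %d steps from (%d,%d)>\n", length(x$codes),
              x$start[1], x$start[2]))
  invisible(x)
}

#' Binarize a grayscale image and keep the main silhouette
#'
#' Thresholds a single-channel image (Otsu's histogram threshold unless one
#' is supplied), keeps the largest foreground connected component, and fills
#' interior holes.
#'
#' @param image numeric matrix (any range) or an `EBImage` image.
#' @param threshold optional threshold on the rescaled 0..1 intensities.
#' @param foreground `"bright"` (default) if the object is lighter than the
#'   background, `"dark"` otherwise.
#' @return A logical mask matrix.
#' @export
binarize <- function(image, threshold = NULL,
                     foreground = c("bright", "dark")) {
  foreground <- match.arg(foreground)
  img <- if (inherits(image, "Image")) EBImage::imageData(image) else
    as.matrix(image)
  if (length(dim(img)) > 2L) abort("`image` must be single-channel")
  rng <- range(img)
  img01 <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  if (diff(rng) == 0) abort("empty foreground: image is constant")
  thr <- threshold %||% EBImage::otsu(EBImage::Image(img01))
  mask <- if (foreground == "bright") img01 >= thr else img01 < thr
  if (!any(mask)) abort("empty foreground after thresholding")
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  labm <- EBImage::imageData(lab)
  sizes <- tabulate(labm[labm > 0])
  biggest <- which.max(sizes)
  mask <- labm == biggest
  mask <- EBImage::imageData(EBImage::fillHull(EBImage::Image(mask * 1))) > 0
  matrix(mask, nrow = nrow(img))
}

#' Trace the outer boundary of a binary region as a Freeman chain code
#'
#' Moore-neighbour tracing with Jacob's stopping criterion, oriented so the
#' resulting contour is counterclockwise in mathematical coordinates.
#'
#' @param mask logical matrix with a single 8-connected foreground
#'   component.
#' @return A [chaincode()].
#' @export
trace_chain <- function(mask) {
  mask <- as.matrix(mask) > 0
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  start <- NULL
  for (r in seq_len(nr)) {
    c <- which(mask[r, ])[1]
    if (!is.na(c)) { start <- c(r, c); break }
  }
  if (is.null(start)) abort("empty mask")
  # clockwise neighbour order in image coordinates, starting west
  nb <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
              c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  nb_pos <- function(dp) which(nb[, 1] == dp[1] & nb[, 2] == dp[2])

  p <- start
  b <- start + c(0, -1)   # backtrack: pixel scanned just before the start
  first_move <- NULL
  pixels <- list(start)
  codes <- integer(0)
  max_steps <- 8L * sum(mask) + 8L
  for (step in seq_len(max_steps)) {
    k0 <- nb_pos(b - p)
    found <- FALSE
    for (j in seq_len(8L)) {
      k <- ((k0 - 1L + j - 1L) %% 8L) + 1L
      q <- p + nb[k, ]
      if (fg(q[1], q[2])) {
        bprev <- p + nb[((k - 2L) %% 8L) + 1L, ]
        dp <- q - p
        codes <- c(codes, chain_code_of(dp))
        if (is.null(first_move)) first_move <- dp
        b <- bprev
        p <- q
        pixels[[length(pixels) + 1L]] <- p
        found <- TRUE
        break
      }
    }
    if (!found) abort("degenerate region: isolated pixel")
    if (all(p == start) && length(codes) > 1L) {
      # Jacob's criterion: stop when re-entering the start the same way
      nxt <- next_move_preview(p, b, nb, fg)
      if (!is.null(nxt) && all(nxt == first_move)) break
    }
  }
  cc <- chaincode(start, codes)
  # counterclockwise in math coordinates (y = -row)
  ctr <- chain_to_contour(cc)
  if (polygon_area(ctr) < 0) cc <- reverse_chain(cc)
  cc
}

chain_code_of <- function(dp) {
  which(freeman_moves[, 1] == dp[1] & freeman_moves[, 2] == dp[2]) - 1L
}

next_move_preview <- function(p, b, nb, fg) {
  k0 <- which(nb[, 1] == (b - p)[1] & nb[, 2] == (b - p)[2])
  for (j in seq_len(8L)) {
    k <- ((k0 - 1L + j - 1L) %% 8L) + 1L
    q <- p + nb[k, ]
    if (fg(q[1], q[2])) return(q - p)
  }
  NULL
}

reverse_chain <- function(cc) {
  disp <- freeman_moves[cc$codes + 1L, , drop = FALSE]
  end <- cc$start  # closed, so reversal starts at the same pixel
  rcodes <- rev((cc$codes + 4L) %% 8L)
  chaincode(end, rcodes)
}

#' Convert a chain code to a contour polygon
#'
#' Pixel positions are mapped to mathematical coordinates
#' (`x = col`, `y = -row`).
#'
#' @param cc a [chaincode()].
#' @return An `n x 2` contour matrix (one vertex per boundary pixel visit).
#' @export
chain_to_contour <- function(cc) {
  stopifnot(inherits(cc, "chaincode"))
  disp <- freeman_moves[cc$codes + 1L, , drop = FALSE]
  rr <- cc$start[1] + cumsum(c(0, disp[-nrow(disp), 1]))
  ccol <- cc$start[2] + cumsum(c(0, disp[-nrow(disp), 2]))
  cbind(x = ccol, y = -rr)
}

#' Read and write chain-code text files
#'
#' One record per outline: a header line `id length` followed by a line of
#' digits 0-7 (the format used by chain-code based outline software).
#'
#' @param path file path.
#' @return `read_chain_file()`: a named list of [chaincode()] objects.
#' @export
read_chain_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(hdr) < 2L) abort(sprintf("malformed chain-code header: '%s'", lines[i]))
    id <- hdr[1]
    len <- as.integer(hdr[2])
    digits <- character(0)
    i <- i + 1L
    while (sum(nchar(digits)) < len) {
      if (i > length(lines)) abort(sprintf("truncated chain code for '%s'", id))
      digits <- c(digits, gsub("\\s", "", lines[i]))
      i <- i + 1L
    }
    codes <- as.integer(strsplit(paste(digits, collapse = ""), "")[[1]])
    out[[id]] <- chaincode(c(0L, 0L), codes)
  }
  out
}

#' @rdname read_chain_file
#' @param chains named list of [chaincode()] objects.
#' @export
write_chain_file <- function(chains, path) {
  lines <- unlist(lapply(names(chains), function(id) {
    cc <- chains[[id]]
    c(sprintf("%s %d", id, length(cc$codes)),
      paste(cc$codes, collapse = ""))
  }))
  writeLines(lines, path)
  invisible(path)
}
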
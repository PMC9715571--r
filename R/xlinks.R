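# Crosslink restraints: parsing, FDR filtering, classification, and
# distance scoring against a coordinate model.

#' Parse a crosslink residue-pair table
#'
#' Reads a CSV of crosslinked residue pairs (BS3-style CXMS output) with
#' header columns \code{protein1,residue1,protein2,residue2} and optional
#' \code{fdr} and \code{spectra}. Lines starting with \code{#} are
#' comments. Rows exceeding the FDR threshold are dropped (count
#' recorded); duplicate unordered pairs are merged, keeping the maximum
#' spectral count and minimum FDR, in file order of first occurrence.
#'
#' @param path CSV path, or a data.frame with the same columns.
#' @param fdr_threshold retain links with \code{fdr <= fdr_threshold}
#'   (links without an FDR column are always retained). Default 0.05.
#' @return object of class \code{xl_set}: list with \code{links}
#'   (data.frame protein_a, residue_a, protein_b, residue_b, fdr,
#'   spectra), \code{fdr_threshold}, \code{n_dropped_fdr},
#'   \code{provenance}.
#' @export
parse_crosslinks <- function(path, fdr_threshold = 0.05) {
  if (is.data.frame(path)) {
    d <- path
    prov <- "in-memory table"
  } else {
    if (!file.exists(path)) stop("crosslink file not found: ", path)
    d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         strip.white = TRUE)
    prov <- path
  }
  need <- c("protein1", "residue1", "protein2", "residue2")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("crosslink table missing columns: ", paste(missing, collapse = ", "))
  for (col in c("residue1", "residue2")) {
    raw <- as.character(d[[col]])
    v <- suppressWarnings(as.integer(raw))
    bad <- which(is.na(v) | v != suppressWarnings(as.numeric(raw)))
    if (length(bad))
      stop("non-integer residue number in column ", col, ", row ", bad[1])
    d[[col]] <- v
  }
  if (any(d$residue1 < 1 | d$residue2 < 1))
    stop("residue numbers must be >= 1")
  if (is.null(d$fdr)) d$fdr <- NA_real_ else d$fdr <- as.numeric(d$fdr)
  if (is.null(d$spectra)) d$spectra <- NA_integer_
  else d$spectra <- as.integer(d$spectra)

  pass <- is.na(d$fdr) | d$fdr <= fdr_threshold
  n_dropped <- sum(!pass)
  if (n_dropped > 0)
    message(n_dropped, " link(s) dropped at FDR threshold ", fdr_threshold)
  d <- d[pass, , drop = FALSE]

  # unordered dedup: canonical key sorts the two (protein, residue) ends
  end_a <- paste(d$protein1, d$residue1)
  end_b <- paste(d$protein2, d$residue2)
  key <- ifelse(end_a <= end_b, paste(end_a, end_b, sep = "|"),
                paste(end_b, end_a, sep = "|"))
  links <- NULL
  for (k in unique(key)) {
    rows <- d[key == k, , drop = FALSE]
    first <- rows[1, ]
    links <- rbind(links, data.frame(
      protein_a = first$protein1, residue_a = first$residue1,
      protein_b = first$protein2, residue_b = first$residue2,
      fdr = if (all(is.na(rows$fdr))) NA_real_ else
        min(rows$fdr, na.rm = TRUE),
      spectra = if (all(is.na(rows$spectra))) NA_integer_ else
        max(rows$spectra, na.rm = TRUE),
      stringsAsFactors = FALSE))
  }
  rownames(links) <- NULL
  structure(list(links = links, fdr_threshold = fdr_threshold,
                 n_dropped_fdr = n_dropped, provenance = prov),
            class = "xl_set")
}

#' @export
print.xl_set <- function(x, ...) {
  cat(sprintf("<xl_set> %d unique links (FDR <= %g; %d dropped)\n",
              nrow(x$links), x$fdr_threshold, x$n_dropped_fdr))
  if (!is.null(x$links$kind))
    print(table(kind = x$links$kind, status = x$links$status))
  invisible(x)
}

#' Classify crosslinks as inter- or intra-subunit and map them
#'
#' Assigns \code{kind} (\code{intra_subunit} when the two ends name the
#' same protein, else \code{inter_subunit}) and \code{status}
#' (\code{mapped} when both ends have at least one model address under the
#' chain map, else \code{unmapped}). Unmapped links are flagged and
#' counted, never dropped: links into disordered or absent regions remain
#' part of the accounting.
#'
#' @param xl \code{xl_set}.
#' @param cmap \code{xl_chainmap}.
#' @return \code{xl_set} with \code{kind} and \code{status} columns and a
#'   \code{counts} element (n_inter, n_intra, n_unmapped, n_total).
#' @export
classify_links <- function(xl, cmap) {
  l <- xl$links
  n <- nrow(l)
  kind <- ifelse(l$protein_a == l$protein_b, "intra_subunit",
                 "inter_subunit")
  status <- character(n)
  for (i in seq_len(n)) {
    ma <- map_residue(cmap, l$protein_a[i], l$residue_a[i])
    mb <- map_residue(cmap, l$protein_b[i], l$residue_b[i])
    status[i] <- if (nrow(ma) > 0 && nrow(mb) > 0) "mapped" else "unmapped"
  }
  l$kind <- kind
  l$status <- status
  xl$links <- l
  xl$counts <- c(
    n_inter = sum(kind == "inter_subunit" & status == "mapped"),
    n_intra = sum(kind == "intra_subunit" & status == "mapped"),
    n_unmapped = sum(status == "unmapped"),
    n_total = n)
  xl
}

#' C-alpha distances for crosslinks against a model
#'
#' Computes the Euclidean CA-CA distance of every mappable link. When a
#' homodimer makes an end ambiguous (several chain copies), the copy
#' combination giving the shortest distance is used -- the standard
#' permissive convention, since CXMS cannot distinguish identical chains;
#' the chosen addresses are recorded. A link is satisfied when its
#' distance is at most \code{cutoff} (inclusive boundary).
#'
#' @param model \code{xl_structure}.
#' @param xl \code{xl_set} (classified or not; classification is applied
#'   if absent).
#' @param cmap \code{xl_chainmap}.
#' @param cutoff satisfaction cutoff in Angstrom. Default 30, the
#'   field-standard CA-CA bound for the BS3 crosslinker (11.4 A spacer
#'   plus two lysine side chains and backbone flexibility).
#' @return data.frame of class \code{xl_distances}: one row per link with
#'   chosen addresses, \code{distance}, \code{mappable},
#'   \code{satisfied}, \code{kind}; attribute \code{cutoff}.
#' @export
link_distances <- function(model, xl, cmap, cutoff = 30.0) {
  stopifnot(cutoff > 0)
  if (is.null(xl$links$kind)) xl <- classify_links(xl, cmap)
  l <- xl$links
  ca <- ca_coords(model)
  addr <- attr(ca, "address")
  ca_key <- paste(addr$chain, addr$resno)

  res <- data.frame(l[, c("protein_a", "residue_a", "protein_b",
                          "residue_b", "kind")],
                    chain_a = NA_character_, resno_a = NA_integer_,
                    chain_b = NA_character_, resno_b = NA_integer_,
                    distance = NA_real_, mappable = FALSE,
                    satisfied = NA, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(l))) {
    ma <- map_residue(cmap, l$protein_a[i], l$residue_a[i])
    mb <- map_residue(cmap, l$protein_b[i], l$residue_b[i])
    ia <- match(paste(ma$chain, ma$resno), ca_key)
    ib <- match(paste(mb$chain, mb$resno), ca_key)
    ma <- ma[!is.na(ia), , drop = FALSE]; ia <- ia[!is.na(ia)]
    mb <- mb[!is.na(ib), , drop = FALSE]; ib <- ib[!is.na(ib)]
    if (length(ia) == 0L || length(ib) == 0L) next
    best <- c(Inf, NA, NA)
    for (p in seq_along(ia)) for (q in seq_along(ib)) {
      if (ia[p] == ib[q]) next  # same atom: not a crosslinkable pair
      dd <- sqrt(sum((ca[ia[p], ] - ca[ib[q], ])^2))
      if (dd < best[1]) best <- c(dd, p, q)
    }
    if (!is.finite(best[1])) next
    res$chain_a[i] <- ma$chain[best[2]]; res$resno_a[i] <- ma$resno[best[2]]
    res$chain_b[i] <- mb$chain[best[3]]; res$resno_b[i] <- mb$resno[best[3]]
    res$distance[i] <- best[1]
    res$mappable[i] <- TRUE
    res$satisfied[i] <- best[1] <= cutoff
  }
  attr(res, "cutoff") <- cutoff
  class(res) <- c("xl_distances", "data.frame")
  res
}

#' Restraint satisfaction fraction
#'
#' Fraction of mappable links with CA-CA distance within the cutoff, with
#' a per-kind breakdown.
#'
#' @param distances \code{xl_distances} from \code{\link{link_distances}}.
#' @return list: \code{fraction}, \code{n_satisfied}, \code{n_violated},
#'   \code{n_unmappable}, \code{by_kind} (data.frame).
#' @export
satisfaction_fraction <- function(distances) {
  d <- distances[distances$mappable, , drop = FALSE]
  if (nrow(d) == 0L) stop("no mappable links")
  by_kind <- do.call(rbind, lapply(split(d, d$kind), function(g)
    data.frame(kind = g$kind[1], n = nrow(g), n_satisfied = sum(g$satisfied),
               fraction = mean(g$satisfied), stringsAsFactors = FALSE)))
  rownames(by_kind) <- NULL
  list(fraction = mean(d$satisfied),
       n_satisfied = sum(d$satisfied),
       n_violated = sum(!d$satisfied),
       n_unmappable = sum(!distances$mappable),
       by_kind = by_kind)
}

#' Write a crosslink set to CSV
#' @param xl \code{xl_set}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_crosslinks <- function(xl, path) {
  l <- xl$links
  out <- data.frame(protein1 = l$protein_a, residue1 = l$residue_a,
                    protein2 = l$protein_b, residue2 = l$residue_b,
                    fdr = l$fdr, spectra = l$spectra)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
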
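#' Write / read the delimited genotype table
#'
#' The pipeline's genotype exchange format is tab-separated with one row per
#' locus: `locus_id`, `seg_type`, the two parental genotypes (`P1`, `P2`,
#' allele sizes as `a1/a2`, 0 = null), then one column per progeny with the
#' observed call — `a1/a2` for two visible alleles, `a/0` for one, `-` for
#' missing.
#'
#' @param pop A `clover_population` (or a list with `loci` and `calls`).
#' @param path Output / input file path.
#' @return `write_genotype_table()` returns `path` invisibly;
#'   `read_genotype_table()` returns a list with `loci` (tibble `locus_id`,
#'   `seg_type`, `p1_a1`..`p2_a2`) and `calls` (long tibble `locus_id`,
#'   `indiv`, `a1`, `a2`) usable by [transmission_matrix()].
#' @export
write_genotype_table <- function(pop, path) {
  loci <- pop$loci; calls <- pop$calls
  inds <- sort(unique(calls$indiv))
  enc <- ifelse(is.na(calls$a1), "-",
                ifelse(is.na(calls$a2), paste0(calls$a1, "/0"),
                       paste0(calls$a1, "/", calls$a2)))
  wide <- matrix("-", nrow(loci), length(inds),
                 dimnames = list(loci$locus_id, inds))
  wide[cbind(match(calls$locus_id, loci$locus_id),
             match(calls$indiv, inds))] <- enc
  header <- c("locus_id", "seg_type", "P1", "P2", inds)
  body <- cbind(loci$locus_id, loci$seg_type,
                paste0(loci$p1_a1, "/", loci$p1_a2),
                paste0(loci$p2_a1, "/", loci$p2_a2), wide)
  writeLines(c(paste(header, collapse = "\t"),
               apply(body, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' @rdname write_genotype_table
#' @export
read_genotype_table <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  header <- lines[[1]]
  stopifnot(identical(header[1:4], c("locus_id", "seg_type", "P1", "P2")))
  inds <- header[-(1:4)]
  body <- do.call(rbind, lines[-1])
  split_pair <- function(x) {
    m <- stringr::str_split_fixed(x, "/", 2)
    cbind(as.numeric(m[, 1]), as.numeric(m[, 2]))
  }
  p1 <- split_pair(body[, 3]); p2 <- split_pair(body[, 4])
  loci <- tibble(
    locus_id = body[, 1], seg_type = body[, 2],
    p1_a1 = p1[, 1], p1_a2 = p1[, 2], p2_a1 = p2[, 1], p2_a2 = p2[, 2]
  )
  callm <- body[, -(1:4), drop = FALSE]
  long <- tibble(
    locus_id = rep(loci$locus_id, times = length(inds)),
    indiv = rep(inds, each = nrow(loci)),
    raw = as.vector(callm)
  )
  a1 <- rep(NA_real_, nrow(long))
  a2 <- rep(NA_real_, nrow(long))
  ok <- long$raw != "-"
  sp <- stringr::str_split_fixed(long$raw[ok], "/", 2)
  a1[ok] <- as.numeric(sp[, 1])
  a2[ok] <- as.numeric(sp[, 2])
  a2[!is.na(a2) & a2 == 0] <- NA_real_
  long <- long %>%
    dplyr::mutate(a1 = a1, a2 = a2) %>%
    dplyr::select("locus_id", "indiv", "a1", "a2")
  list(loci = loci, calls = long)
}

#' Read a JoinMap-style CP locus file
#'
#' Minimal reader for the classic CP-population `.loc` coding for
#' interoperability: lines of the form
#' `name <abxcd> ac ad bc bd ...` with segregation codes `<abxcd>`,
#' `<efxeg>`, `<hkxhk>`, `<lmxll>`, `<nnxnp>` and `--` or `.` for missing
#' calls.  Allele letters are translated to synthetic allele sizes (two
#' base pairs apart, per locus) so the result plugs into the same pipeline
#' as size-scored SSR data.
#'
#' @param path Path to the locus file.
#' @return A list with `loci` and `calls` shaped as in
#'   [read_genotype_table()].
#' @export
read_joinmap_loc <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, ";")]
  code_map <- list(
    "<abxcd>" = list(p1 = c("a", "b"), p2 = c("c", "d"), type = "abxcd"),
    "<efxeg>" = list(p1 = c("e", "f"), p2 = c("e", "g"), type = "abxac"),
    "<hkxhk>" = list(p1 = c("h", "k"), p2 = c("h", "k"), type = "abxab"),
    "<lmxll>" = list(p1 = c("l", "m"), p2 = c("l", "l"), type = "abxaa"),
    "<nnxnp>" = list(p1 = c("n", "n"), p2 = c("n", "p"), type = "aaxab")
  )
  loci <- list(); calls <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) < 3 || !parts[2] %in% names(code_map)) {
      stop("unrecognised .loc line: ", ln, call. = FALSE)
    }
    cm <- code_map[[parts[2]]]
    letters_used <- sort(unique(c(cm$p1, cm$p2)))
    size_of <- setNames(100 + 2 * seq_along(letters_used), letters_used)
    p1 <- size_of[cm$p1]; p2 <- size_of[cm$p2]
    obs <- parts[-(1:2)]
    dec <- lapply(obs, function(o) {
      if (o %in% c("--", ".", "-")) return(c(NA_real_, NA_real_))
      sizes <- sort(unique(size_of[strsplit(o, "")[[1]]]))
      if (anyNA(sizes)) return(c(NA_real_, NA_real_))
      c(sizes[1], if (length(sizes) > 1) sizes[2] else NA_real_)
    })
    id <- parts[1]
    loci[[id]] <- tibble(locus_id = id, seg_type = cm$type,
                         p1_a1 = unname(p1[1]), p1_a2 = unname(p1[2]),
                         p2_a1 = unname(p2[1]), p2_a2 = unname(p2[2]))
    calls[[id]] <- tibble(
      locus_id = id,
      indiv = sprintf("F1_%03d", seq_along(dec)),
      a1 = vapply(dec, `[`, double(1), 1),
      a2 = vapply(dec, `[`, double(1), 2)
    )
  }
  list(loci = dplyr::bind_rows(loci), calls = dplyr::bind_rows(calls))
}

#' Write / read a map table
#'
#' Tab-separated map exchange format: `locus_id`, `group`, `pos_cM`.
#'
#' @param map A `clover_map` or map tibble.
#' @param path File path.
#' @return The path (write) or a map tibble (read).
#' @export
write_map_table <- function(map, path) {
  loci <- if (inherits(map, "clover_map")) map$loci else map
  utils::write.table(loci[, c("locus_id", "group", "pos_cM")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_table
#' @export
read_map_table <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}

#' Write the simulation truth table
#'
#' Delimited truth labels for a simulated experiment: one row per locus per
#' population with `marker_id`, `locus_id`, `population`, `group`,
#' `homoeologue`, `pos_cM`, `seg_type`, `joining`.
#'
#' @param cross A `clover_cross` from [simulate_cross()].
#' @param path File path.
#' @export
write_truth_table <- function(cross, path) {
  truth <- dplyr::bind_rows(lapply(cross$populations, function(p) {
    dplyr::mutate(p$loci[, c("marker_id", "locus_id", "group", "homoeologue",
                             "pos_cM", "seg_type", "joining")],
                  population = p$population, .before = 1)
  }))
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
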
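# Orchestration: configuration, the five-gene synthetic preset and the
# end-to-end pipeline (classify proteins, scan UTRs, call SOPEs, integrate
# gene-level labels, pool per-box logos, write reports).

#' Build a run configuration
#'
#' @param boxes `"default"` or a list of [box_definition()] objects.
#' @param cluster A [cluster_params()] object.
#' @param cterm_min C-terminal identity threshold for the ASH call.
#' @param classes An [aa_class_config()].
#' @param pairing Data frame with columns `protein_id`, `transcript_id`
#'   mapping each protein to at most one transcript (`NULL`: pair by
#'   identical ids).
#' @param orf_table Optional data frame with columns `transcript_id`,
#'   `start`, `end` (0-based half-open) of known ORFs; transcripts absent
#'   from the table get an inferred ORF.
#' @param scan_region `"utr"` (default: hits inside the ORF are excluded)
#'   or `"transcript"`.
#' @param seed Integer seed governing all randomness in the run.
#' @param out_dir Optional output directory for BED/TSV/JSON files.
#' @return An object of class `run_config`.
#' @export
run_config <- function(boxes = "default", cluster = cluster_params(),
                       cterm_min = 0.5, classes = aa_class_config(),
                       pairing = NULL, orf_table = NULL,
                       scan_region = c("utr", "transcript"),
                       seed = 1L, out_dir = NULL) {
  scan_region <- match.arg(scan_region)
  if (identical(boxes, "default")) boxes <- default_box_set()
  stopifnot(is.list(boxes), inherits(cluster, "cluster_params"),
            inherits(classes, "aa_class_config"),
            cterm_min >= 0, cterm_min <= 1)
  structure(list(boxes = boxes, cluster = cluster, cterm_min = cterm_min,
                 classes = classes, pairing = pairing, orf_table = orf_table,
                 scan_region = scan_region, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys: `boxes` (either the string `default` or a map of
#' name -> definition with fields `kind`, `pattern` or
#' `width`/`min_at_fraction`, `both_strands`), `cluster`
#' (`gap_max`, `min_boxes`, `min_types`), `cterm_min`, `classes`
#' (`hydrophobic`, `polar` as strings), `scan_region`, `seed`,
#' `out_dir`, `pairing` (list of `{protein_id, transcript_id}`) and
#' `orf_table` (list of `{transcript_id, start, end}`).
#'
#' @param path Path to a YAML config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  boxes <- if (is.null(y$boxes) || identical(y$boxes, "default")) {
    default_box_set()
  } else {
    out <- lapply(names(y$boxes), function(nm) {
      b <- y$boxes[[nm]]
      box_definition(nm, kind = b$kind %||% "iupac_pattern",
                     pattern = b$pattern, width = b$width,
                     min_at_fraction = b$min_at_fraction,
                     both_strands = b$both_strands %||% TRUE)
    })
    stats::setNames(out, names(y$boxes))
  }
  cl <- y$cluster %||% list()
  classes <- if (is.null(y$classes)) aa_class_config() else {
    aa_class_config(strsplit(y$classes$hydrophobic, "")[[1]],
                    strsplit(y$classes$polar, "")[[1]])
  }
  to_df <- function(x) if (is.null(x)) NULL else
    do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  run_config(
    boxes = boxes,
    cluster = cluster_params(cl$gap_max %||% 450L, cl$min_boxes %||% 4L,
                             cl$min_types %||% 3L),
    cterm_min = y$cterm_min %||% 0.5,
    classes = classes,
    pairing = to_df(y$pairing),
    orf_table = to_df(y$orf_table),
    scan_region = y$scan_region %||% "utr",
    seed = y$seed %||% 1L,
    out_dir = y$out_dir
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# geometry of the five published arthropod SOPEs: per-species box
# composition and ORF-relative location (5' distances are upstream of the
# start codon, 3' distances downstream of the stop codon)
.arthropod_five_geometry <- function() {
  list(
    Dm = list(side = "five_prime", utr = 500L, other = 60L,
              # 4 E, 2 alpha, 1 beta, 1 N over 297 bp ending 144 bp upstream
              boxes = data.frame(
                box = c("E", "E", "alpha", "beta", "N", "alpha", "E", "E"),
                offset = c(59L, 120L, 170L, 220L, 260L, 300L, 330L, 350L),
                stringsAsFactors = FALSE)),
    Tc = list(side = "five_prime", utr = 400L, other = 60L,
              # 3 E, 2 alpha, 5 beta, 1 N over 247 bp starting 95 bp upstream
              boxes = data.frame(
                box = c("E", "beta", "alpha", "beta", "E", "beta", "N",
                        "beta", "alpha", "E", "beta"),
                offset = c(58L, 80L, 110L, 140L, 170L, 200L, 230L, 255L,
                           275L, 287L, 297L),
                stringsAsFactors = FALSE)),
    Dp = list(side = "five_prime", utr = 1940L, other = 60L,
              # 1 E, 1 alpha, 2 beta, 1 N over 882 bp, 1,048 bp upstream
              boxes = data.frame(
                box = c("E", "beta", "alpha", "beta", "N"),
                offset = c(10L, 200L, 450L, 700L, 886L),
                stringsAsFactors = FALSE)),
    Cs = list(side = "three_prime", utr = 400L, other = 60L,
              # 3 E, 1 alpha, 1 beta over 246 bp, 3-249 bp downstream
              boxes = data.frame(
                box = c("E", "alpha", "beta", "E", "E"),
                offset = c(3L, 60L, 120L, 180L, 243L),
                stringsAsFactors = FALSE)),
    Sm = list(side = "five_prime", utr = 650L, other = 60L,
              # 4 E, 3 alpha, 5 beta, 1 N between 36 and 601 bp upstream
              boxes = data.frame(
                box = c("E", "beta", "alpha", "beta", "E", "beta", "alpha",
                        "beta", "N", "E", "beta", "alpha", "E"),
                offset = c(49L, 100L, 150L, 200L, 250L, 300L, 350L, 400L,
                           450L, 500L, 540L, 570L, 608L),
                stringsAsFactors = FALSE))
  )
}

.arthropod_five_proteins <- function() {
  # Dm/Tc/Dp carry the Ase motif; Cs is indeterminate on protein evidence
  # alone (30%-class C-terminal identity, no motif); Sm is an ASH protein
  # (62%-class identity, no motif) whose gene nevertheless carries a SOPE
  list(
    Dm = list(label = "ase", k = 7L, motif = TRUE),
    Tc = list(label = "ase", k = 6L, motif = TRUE),
    Dp = list(label = "ase", k = 7L, motif = TRUE),
    Cs = list(label = "indeterminate", k = 4L, motif = FALSE),
    Sm = list(label = "ASH", k = 10L, motif = FALSE)
  )
}

#' Simulate the five-species study bundle
#'
#' Generates five synthetic genes emulating the published five-species
#' configuration: three genes with Ase-motif proteins and 5' UTR SOPEs
#' (fruit fly, beetle, water flea), one gene with an indeterminate
#' protein and a 3' UTR SOPE (spider) and one gene with an ASH protein
#' and a 5' UTR SOPE (centipede). Box compositions, spans and
#' ORF-relative locations follow the published per-species arrangements;
#' concrete box instances are drawn from the consensus definitions
#' (seeded), with one exact `CAGCTG` E box per gene.
#'
#' @param seed Integer seed.
#' @param orf_length ORF length (bp) of every synthetic transcript.
#' @return A list of class `arthropod_five_bundle` with `transcripts` and
#'   `proteins` data frames (FASTA-ready), a `pairing` data frame, an
#'   `orf_table`, and `truth` (per-gene planted evidence).
#' @export
simulate_arthropod_five <- function(seed = 1L, orf_length = 300L) {
  geom <- .arthropod_five_geometry()
  prot <- .arthropod_five_proteins()
  defs <- default_box_set()
  transcripts <- proteins <- list()
  truth <- list()
  for (g in names(geom)) {
    gi <- which(names(geom) == g)
    sg <- .sub_seed(seed, gi)
    spec_ <- geom[[g]]
    pb <- spec_$boxes
    first_e <- which(pb$box == "E")[1L]
    inst <- vapply(seq_len(nrow(pb)), function(j) {
      d <- defs[[pb$box[j]]]
      if (d$kind == "at_rich_window") strrep("AT", ceiling(d$width / 2))
      else if (j == first_e) "CAGCTG"  # the pooled arthropod E-box logo
      else draw_instance(d$pattern, .sub_seed(sg, j))
    }, "")
    pb$instance <- inst
    plan <- plant_plan(spec_$side, pb, utr_length = spec_$utr,
                       other_utr_length = spec_$other, defs = defs)
    st <- synth_transcript(plan, orf_length = orf_length, seed = sg,
                           id = paste0(g, "_transcript"))
    pr <- prot[[g]]
    sp <- synth_protein(pr$label, pr$k, pr$motif, length = 200L,
                        seed = .sub_seed(sg, 777L), id = paste0(g, "_protein"))
    transcripts[[g]] <- st$record
    proteins[[g]] <- sp$record
    truth[[g]] <- list(transcript = st$truth, protein = sp$truth)
  }
  as_df <- function(recs) data.frame(
    id = vapply(recs, `[[`, "", "id"),
    sequence = vapply(recs, `[[`, "", "sequence"),
    description = vapply(recs, `[[`, "", "description"),
    stringsAsFactors = FALSE, row.names = NULL)
  tdf <- as_df(transcripts); pdf <- as_df(proteins)
  structure(list(
    transcripts = tdf, proteins = pdf,
    pairing = data.frame(protein_id = pdf$id, transcript_id = tdf$id,
                         stringsAsFactors = FALSE),
    orf_table = data.frame(
      transcript_id = tdf$id,
      start = vapply(truth, function(x) x$transcript$orf[1L], 0L),
      end = vapply(truth, function(x) x$transcript$orf[2L], 0L),
      row.names = NULL, stringsAsFactors = FALSE),
    truth = truth
  ), class = "arthropod_five_bundle")
}

#' Run the full classification and SOPE-detection pipeline
#'
#' Per gene: measures the two diagnostic protein motifs and classifies
#' the protein; locates the ORF (provided coordinates or inferred),
#' derives the UTRs, scans them for box hits, calls SOPE candidate
#' clusters and localizes them relative to the ORF; integrates protein
#' and regulatory evidence into the gene-level label. Across genes,
#' box instances belonging to called clusters are pooled per box class
#' into frequency matrices and logo tracks (reverse-strand instances are
#' orientation-corrected; variable-width AT-rich regions are not pooled).
#'
#' Proteins without a paired transcript get a warning and indeterminate
#' regulatory evidence. The JSON summary is a deterministic function of
#' `(inputs, config)`.
#'
#' @param transcripts Path to a transcript FASTA file, or a data frame as
#'   returned by [read_fasta()].
#' @param proteins Path to a protein FASTA file, or a data frame.
#' @param config A [run_config()].
#' @return An object of class `sope_report`: `genes` (one row per
#'   protein: ids, protein evidence, SOPE evidence, integrated label),
#'   `hits` and `clusters` (named per-transcript lists), `logos` (named
#'   per-box-class `logo_track` list), `json` (the summary as a JSON
#'   string). Files are written when the config has an `out_dir`.
#' @export
run_pipeline <- function(transcripts, proteins, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(transcripts)) transcripts <- read_fasta(transcripts, "dna")
  if (is.character(proteins)) proteins <- read_fasta(proteins, "protein")

  if (nrow(transcripts) == 0L) warning("no transcript records in input")
  pairing <- config$pairing %||% data.frame(
    protein_id = proteins$id,
    transcript_id = ifelse(proteins$id %in% transcripts$id, proteins$id, NA),
    stringsAsFactors = FALSE)

  # per-transcript scanning and cluster calling
  hits_by_tx <- list(); clusters_by_tx <- list(); orf_by_tx <- list()
  for (i in seq_len(nrow(transcripts))) {
    id <- transcripts$id[i]; seq_ <- transcripts$sequence[i]
    provided <- NULL
    if (!is.null(config$orf_table)) {
      row <- config$orf_table[config$orf_table$transcript_id == id, , drop = FALSE]
      if (nrow(row) == 1L) provided <- c(row$start, row$end)
    }
    ann <- find_orf(seq_, provided)
    orf_by_tx[[id]] <- ann
    if (is.null(ann$orf)) {
      hits_by_tx[[id]] <- .empty_hits()
      clusters_by_tx[[id]] <- call_clusters(.empty_hits(), config$cluster)
      next
    }
    regions <- if (config$scan_region == "transcript") {
      list(whole = c(0L, nchar(seq_)))
    } else {
      Filter(Negate(is.null), extract_utrs(seq_, ann))
    }
    hit_parts <- list(); cluster_parts <- list()
    for (side in names(regions)) {
      reg <- regions[[side]]
      sub <- substr(seq_, reg[1L] + 1L, reg[2L])
      h <- scan_boxes(sub, config$boxes)
      if (nrow(h) > 0L) { h$start <- h$start + reg[1L]; h$end <- h$end + reg[1L] }
      hit_parts[[side]] <- h
      cl <- call_clusters(h, config$cluster)
      if (nrow(cl) > 0L) cluster_parts[[side]] <- cl
    }
    h_all <- do.call(rbind, c(hit_parts, list(make.row.names = FALSE)))
    if (is.null(h_all)) h_all <- .empty_hits()
    class(h_all) <- c("box_hits", "data.frame")
    hits_by_tx[[id]] <- h_all
    cl_all <- if (length(cluster_parts) > 0L) {
      out <- do.call(rbind, c(cluster_parts, list(make.row.names = FALSE)))
      out <- out[order(out$start), , drop = FALSE]
      rownames(out) <- NULL
      class(out) <- c("sope_calls", "data.frame")
      out
    } else {
      call_clusters(.empty_hits(), config$cluster)
    }
    clusters_by_tx[[id]] <- cl_all
  }

  # per-protein evidence and gene-level integration
  gene_rows <- list()
  for (i in seq_len(nrow(proteins))) {
    pid <- proteins$id[i]
    ev <- protein_evidence(proteins$sequence[i], classes = config$classes,
                           cterm_min = config$cterm_min)
    tx <- pairing$transcript_id[match(pid, pairing$protein_id)]
    has_sope <- FALSE; utr_side <- NA_character_; loc <- NA_character_
    sope_start <- NA_integer_; sope_end <- NA_integer_
    if (is.na(tx) || !(tx %in% names(clusters_by_tx))) {
      if (length(tx) == 0L || is.na(tx)) {
        warning(sprintf("protein '%s' has no paired transcript; regulatory evidence indeterminate", pid))
      }
      tx <- NA_character_
    } else {
      cl <- clusters_by_tx[[tx]]
      if (nrow(cl) > 0L) {
        has_sope <- TRUE
        seq_len_tx <- nchar(transcripts$sequence[transcripts$id == tx][1L])
        ld <- localize_sope(c(cl$start[1L], cl$end[1L]),
                            orf_by_tx[[tx]], seq_len_tx)
        utr_side <- ld$utr_side
        loc <- format(ld)
        sope_start <- cl$start[1L]; sope_end <- cl$end[1L]
      }
    }
    gene_rows[[pid]] <- data.frame(
      protein_id = pid, transcript_id = tx,
      protein_label = ev$label,
      cterm_identity = if (is.null(ev$cterm)) NA_real_ else ev$cterm$identity,
      cterm_percent = if (is.null(ev$cterm)) NA_integer_ else ev$cterm$percent,
      n_ase_motif_hits = length(ev$ase_motif_hits),
      has_sope = has_sope, utr_side = utr_side,
      sope_start = sope_start, sope_end = sope_end, sope_location = loc,
      gene_label = integrate_gene_call(ev$label, has_sope),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, c(gene_rows, list(make.row.names = FALSE)))
  if (is.null(genes)) {
    genes <- data.frame(protein_id = character(0), transcript_id = character(0),
                        protein_label = character(0), cterm_identity = numeric(0),
                        cterm_percent = integer(0), n_ase_motif_hits = integer(0),
                        has_sope = logical(0), utr_side = character(0),
                        sope_start = integer(0), sope_end = integer(0),
                        sope_location = character(0), gene_label = character(0),
                        stringsAsFactors = FALSE)
  }

  # pooled per-box-class logos from cluster member sites
  logos <- list()
  fixed_width <- Filter(function(d) d$kind == "iupac_pattern", config$boxes)
  for (nm in names(fixed_width)) {
    sites <- character(0)
    for (cl in clusters_by_tx) {
      if (nrow(cl) == 0L) next
      for (r in seq_len(nrow(cl))) {
        m <- cl$hits[[r]]
        m <- m[m$box == nm, , drop = FALSE]
        if (nrow(m) == 0L) next
        oriented <- ifelse(m$strand == "-",
                           vapply(m$matched, revcomp, ""), m$matched)
        sites <- c(sites, unname(oriented))
      }
    }
    sites <- sites[grepl("^[ACGT]*$", sites)]
    if (length(sites) > 0L) {
      logos[[nm]] <- information_content(build_pfm(site_alignment(sites, nm)))
    }
  }

  summary_list <- list(
    n_transcripts = nrow(transcripts),
    n_proteins = nrow(proteins),
    seed = config$seed,
    cluster_params = unclass(config$cluster),
    genes = genes,
    logo_consensus = lapply(logos, `[[`, "consensus"),
    label_counts = as.list(table(genes$gene_label))
  )
  json <- jsonlite::toJSON(summary_list, auto_unbox = TRUE, digits = 10,
                           na = "null", pretty = TRUE)

  report <- structure(list(genes = genes, hits = hits_by_tx,
                           clusters = clusters_by_tx, logos = logos,
                           orfs = orf_by_tx, json = json,
                           config = config),
                      class = "sope_report")
  if (!is.null(config$out_dir)) .write_report_files(report, transcripts)
  report
}

.write_report_files <- function(report, transcripts) {
  dir.create(report$config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- report$config$out_dir
  for (id in names(report$hits)) {
    h <- report$hits[[id]]
    if (nrow(h) > 0L) {
      write_bed6(h, file.path(od, paste0(id, "_hits.bed")), chrom = id)
      utils::write.table(h, file.path(od, paste0(id, "_hits.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    cl <- report$clusters[[id]]
    if (nrow(cl) > 0L) {
      write_bed6(cl, file.path(od, paste0(id, "_sope.bed")),
                 chrom = id, name_col = "SOPE")
    }
  }
  utils::write.table(report$genes, file.path(od, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$logos)) {
    write_logo_tsv(report$logos[[nm]], file.path(od, paste0("logo_", nm, ".tsv")))
  }
  writeLines(report$json, file.path(od, "summary.json"))
  invisible(od)
}

#' @export
print.sope_report <- function(x, ...) {
  cat(sprintf("SOPE pipeline report: %d gene(s)\n", nrow(x$genes)))
  if (nrow(x$genes) > 0L) {
    print.data.frame(x$genes[, c("protein_id", "protein_label", "cterm_percent",
                                 "has_sope", "utr_side", "gene_label")],
                     row.names = FALSE)
  }
  if (length(x$logos) > 0L) {
    cat("pooled logo consensus:",
        paste(sprintf("%s=%s", names(x$logos),
                      vapply(x$logos, `[[`, "", "consensus")), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
summary.sope_report <- function(object, ...) {
  cat(object$json, "\n")
  invisible(object)
}
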
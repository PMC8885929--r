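test_that("snapshot fixture loads, round-trips, and rejects orphans", {
  snap <- mini_snapshot()
  expect_s3_class(snap, "kegg_snapshot")
  expect_gte(length(snap$compounds), 20L)
  expect_gte(length(snap$genes), 30L)
  expect_length(snap$pathways, 5L)
  # every member resolvable
  for (p in snap$pathways) {
    expect_true(all(p$genes %in% names(snap$genes)))
    expect_true(all(p$compounds %in% names(snap$compounds)))
  }
  expect_true(any(vapply(snap$pathways, function(p)
    grepl("leucine and isoleucine degradation", p$name), logical(1))))

  # reload from cache is identical
  dir <- withr::local_tempdir()
  write_snapshot(snap, dir)
  expect_identical(load_snapshot(dir), snap)

  # dangling member -> error naming the orphan
  bad <- snap
  bad$pathways[[1]]$compounds <- c(bad$pathways[[1]]$compounds, "C99999")
  write_snapshot(bad, dir)
  expect_error(load_snapshot(dir), "C99999")
})

test_that("normalize_name applies case, Greek, dash and stereo rules", {
  expect_equal(normalize_name("L-Valine"), "valine")
  expect_equal(normalize_name("L-Valine", strip_stereo = FALSE), "l-valine")
  expect_equal(normalize_name("β-Alanine"), "beta-alanine")
  expect_equal(normalize_name("  \"Citric–Acid\"  "), "citric-acid")
  expect_equal(normalize_name("DL-Serine"), "serine")
  expect_equal(normalize_name(""), "")
})

test_that("normalize_name is idempotent on fuzzed strings", {
  set.seed(202)
  alphabet <- c(letters, LETTERS, 0:9, " ", "-", "–", "—", "(",
                ")", "'", "\"", ",", ".", "α", "β", "ω",
                "‘", "’")
  fuzz <- vapply(seq_len(1000), function(i)
    paste(sample(alphabet, sample(0:24, 1), replace = TRUE),
          collapse = ""), "")
  fuzz <- c(fuzz, "L-L-Valine", "dl-(s)-thing", "(R)-ALA")
  once <- normalize_name(fuzz)
  expect_identical(normalize_name(once), once)
})

test_that("matching cascade: exact, token and fuzzy stages behave", {
  snap <- mini_snapshot()
  m <- match_metabolite("l-valine", snap)
  expect_equal(m$candidates$compound_id[1], "C00183")
  expect_equal(m$candidates$score[1], 1)

  # token permutation resolves through the token stage; score is the
  # Jaccard of the token sets, computed here by hand: query {valine, l}
  # vs stripped synonym {valine} -> 1/2
  m <- match_metabolite("valine l", snap)
  expect_equal(m$candidates$compound_id[1], "C00183")
  expect_equal(m$candidates$score[1], 0.5)
  expect_lt(max(m$candidates$score), 1)

  # small typo passes the edit-distance stage at the default threshold
  m <- match_metabolite("isoleucin", snap)
  expect_equal(m$candidates$compound_id[1], "C00407")
  expect_gte(m$candidates$score[1], 0.85)
  expect_lt(m$candidates$score[1], 1)

  m <- match_metabolite("zzz-unknown-compound", snap)
  expect_equal(nrow(m$candidates), 0L)

  # exact synonyms of every compound map at score 1 to their own id
  idx_true <- rep(names(snap$compounds), lengths(snap$compounds))
  syns <- unlist(snap$compounds, use.names = FALSE)
  for (i in seq_along(syns)) {
    m <- match_metabolite(syns[i], snap)
    expect_equal(m$candidates$score[1], 1)
    expect_true(idx_true[i] %in%
                  m$candidates$compound_id[m$candidates$score == 1])
  }
})

test_that("metabolite classes collapse to one class-level KEGG id", {
  rules <- data.frame(pattern = c("SM(", "sphingomyelin", "PC("),
                      class_label = c("sphingomyelin", "sphingomyelin",
                                      "phosphatidylcholine"),
                      class_kegg_id = c("C00550", "C00550", "C00157"),
                      stringsAsFactors = FALSE)
  names10 <- c("SM(d18:1/16:0)", "SM(d18:1/24:1)", "Sphingomyelin",
               "PC(16:0/18:1)", "PC(18:0/20:4)", "L-Valine", "Malate",
               "pc(14:0/14:0)", "sm(d18:0/18:0)", "Glutamate")
  cls <- assign_metabolite_class(names10, rules)
  expect_equal(cls$class_label,
               c("sphingomyelin", "sphingomyelin", "sphingomyelin",
                 "phosphatidylcholine", "phosphatidylcholine", NA, NA,
                 "phosphatidylcholine", "sphingomyelin", NA))
  sm <- cls$class_kegg_id[!is.na(cls$class_label) &
                            cls$class_label == "sphingomyelin"]
  expect_true(all(sm == "C00550"))
  # overlapping rules: first wins, logged
  over <- data.frame(pattern = c("alanine", "beta-alanine"),
                     class_label = c("A", "B"),
                     class_kegg_id = c("C1", "C2"))
  expect_message(got <- assign_metabolite_class("beta-Alanine", over),
                 "first")
  expect_equal(got$class_label, "A")
})

test_that("gene mapping resolves aliases, keeps unknowns, flags ambiguity", {
  snap <- mini_snapshot()
  ann <- map_genes(c("bcat-1", "BCAT1", "totally-unknown"), snap)
  expect_equal(nrow(ann), 3L)
  # alias and primary symbol give identical annotation
  expect_equal(ann$kegg_id[1], ann$kegg_id[2])
  expect_equal(ann$pathway_ids[1], ann$pathway_ids[2])
  expect_true(grepl("cel00280", ann$pathway_ids[1]))
  expect_equal(ann$kegg_id[3], "")
  expect_equal(ann$pathway_ids[3], "")

  # an alias shared by two genes is reported once per gene and flagged
  amb <- snap
  amb$genes[["cel:CELE_dup"]] <- c("dupsym", "shared-al")
  amb$genes[["cel:CELE_dup2"]] <- c("dupsym2", "shared-al")
  ann <- map_genes("shared-al", amb)
  expect_equal(nrow(ann), 2L)
  expect_true(all(ann$ambiguous))
})

test_that("pathway annotation fills membership and never drops features", {
  snap <- mini_snapshot()
  names_in <- c("L-Valine", "Succinyl-CoA", "Amylopectin", "nonsense-xyz")
  ann <- annotate_metabolites(names_in, snap)
  expect_equal(nrow(ann), length(names_in))
  expect_equal(ann$feature_id, names_in)
  # compound in several pathways lists them all; set oracle by brute force
  psets <- pathway_sets(ann)
  brute <- vapply(ann$kegg_id, function(k)
    sum(vapply(snap$pathways, function(p) k %in% p$compounds, logical(1))),
    0L, USE.NAMES = FALSE)
  expect_equal(lengths(psets), brute, ignore_attr = TRUE)
  expect_gte(length(psets[["Succinyl-CoA"]]), 2L)
  # KEGG id without pathway retained with empty list
  expect_equal(ann$kegg_id[ann$feature_id == "Amylopectin"], "C00718")
  expect_equal(ann$pathway_ids[ann$feature_id == "Amylopectin"], "")
  # unmatched name retained with empty kegg_id
  expect_equal(ann$kegg_id[4], "")
  # unique-pathway count equals brute-force set union
  expect_equal(length(unique(unlist(psets))),
               length(Reduce(union, psets)))

  # annotation TSV round trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(ann, path)
  back <- read_annotation(path)
  expect_equal(back$kegg_id, ann$kegg_id)
  expect_equal(back$pathway_ids, ann$pathway_ids)
})
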
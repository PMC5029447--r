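test_that("strip_cca removes one trailing CCA exactly, flagging the trim", {
  s79 <- paste0(identity_body(), "GGGCCA")  # 79 nt ending in CCA
  out <- strip_cca(s79)
  expect_equal(nchar(out$sequence), 76L)
  expect_true(out$trimmed)
  expect_equal(strip_cca("AUGCCA")$sequence, "AUG")  # only one CCA removed
  expect_equal(strip_cca("AUGCCACCA")$sequence, "AUGCCA")

  no_tail <- strip_cca("AUGC")
  expect_equal(no_tail$sequence, "AUGC")
  expect_false(no_tail$trimmed)

  degenerate <- strip_cca("CCA")
  expect_equal(degenerate$sequence, "")
  expect_true(degenerate$trimmed)
})

test_that("remove_introns concatenates inter-span segments and rejects bad spans", {
  expect_equal(remove_introns("AAAGGGCCC", matrix(c(3, 6), 1, 2)), "AAACCC")
  expect_equal(remove_introns("AAAGGGCCC"), "AAAGGGCCC")
  expect_equal(remove_introns("AAAGGGCCC", matrix(c(0, 6, 3, 9), 2, 2)),
               "GGG")
  expect_error(remove_introns("AAAGGGCCC", matrix(c(0, 3, 2, 5), 2, 2,
                                                  byrow = TRUE)),
               "overlap")
  expect_error(remove_introns("AAA", matrix(c(1, 5), 1, 2)), "range")
})

test_that("a full-length gene body aligns onto its slots with zero gaps", {
  body <- identity_body("GUG")
  a <- align_to_canonical(body, "GUG", anticodon_start = 33L)
  expect_true(a$ok)
  expect_equal(unname(a$slots[1:73]), strsplit(body, "")[[1]])
  expect_equal(unname(a$slots[74:76]), rep("-", 3))  # CCA slots stay empty
  expect_equal(a$dropped, 0L)
  # localization by unique triplet match agrees
  b <- align_to_canonical(body, "GUG")
  expect_equal(b$slots, a$slots)
})

test_that("D-loop deletions gap the highest-numbered loop anchor slots, stems untouched", {
  body <- strsplit(identity_body("GUG"), "")[[1]]
  # delete two D-loop bases (slots N16, N17); anticodon shifts to 0-based 31
  del <- body[-c(16, 17)]
  a <- align_to_canonical(paste(del, collapse = ""), "GUG",
                          anticodon_start = 31L)
  expect_true(a$ok)
  # hand-placed expectation per the anchor rule: the 17 D-region bases fill
  # N8..N19 and N22..N26 in order; gaps land on N20 and N21
  d_bases <- body[c(8:15, 18:26)]
  expected <- c(body[1:7], d_bases[1:12], "-", "-", d_bases[13:17],
                body[27:73], "-", "-", "-")
  expect_equal(unname(a$slots), expected)
  # all stem slots unchanged
  stems <- c(1:7, 27:33, 37:43, 66:73)
  expect_equal(unname(a$slots[stems]), body[stems])
})

test_that("short TPsiC regions gap the T loop; long variable loops drop overflow", {
  body <- strsplit(identity_body("GUG"), "")[[1]]
  # the TPsiC arm fills from the 3' end, so its loop is gapped only once the
  # whole middle segment runs short: drop the variable loop and 3 T-loop bases
  short_t <- body[-c(44:48, 56:58)]
  a <- align_to_canonical(paste(short_t, collapse = ""), "GUG",
                          anticodon_start = 33L)
  expect_true(a$ok)
  expect_equal(unname(a$slots[44:48]), rep("-", 5))  # variable loop empty
  expect_equal(unname(a$slots[58:60]), rep("-", 3))  # T-loop anchor gaps
  expect_equal(unname(a$slots[49:53]), body[49:53])  # T stem 5' intact
  expect_equal(unname(a$slots[61:65]), body[61:65])  # T stem 3' intact

  long_v <- append(body, c("A", "C", "G"), after = 46)  # 8 variable-loop bases
  b <- align_to_canonical(paste(long_v, collapse = ""), "GUG",
                          anticodon_start = 33L)
  expect_true(b$ok)
  expect_equal(b$dropped, 3L)
  expect_equal(unname(b$slots[49:65]), body[49:65])  # TPsiC refilled intact
})

test_that("unlocatable or ambiguous anticodons and bad lengths are rejected with reasons", {
  body <- identity_body("GUG")
  expect_match(align_to_canonical(body, "AAA")$reason, "not found")
  two_hits <- paste0(substr(body, 1, 50), "GUG",
                     substr(body, 54, nchar(body)))
  expect_match(align_to_canonical(two_hits, "GUG")$reason, "ambiguous")
  expect_match(align_to_canonical(substr(body, 1, 40), "GUG",
                                  anticodon_start = 33L)$reason,
               "outside bounds")
  # anticodon too close to the 5' end
  early <- paste0("AAGUGAA", paste(rep("C", 60), collapse = ""))
  expect_match(align_to_canonical(early, "GUG")$reason, "5' side")
})

test_that("prepare_records separates retained and rejected records", {
  good <- identity_body("GUG")
  recs <- trna_records(
    record_id = c("ok1", "ok2", "bad"),
    species_id = "sp1", phylum = "Phy1",
    amino_acid = c("His", "His", "Tyr"),
    anticodon = c("GUG", "GUG", "AAA"),
    sequence = c(paste0(good, "CCA"), good, identity_body("GUG")),
    anticodon_start = c(33L, 33L, NA))
  al <- prepare_records(recs)
  expect_equal(rownames(al$slots), c("ok1", "ok2"))
  expect_equal(al$rejects$record_id, "bad")
  expect_match(al$rejects$reason, "not found")
  # CCA-trimmed and untrimmed full-length bodies align identically
  expect_equal(al$slots[1, ], al$slots[2, ])
})

test_that("alignment is per-record deterministic and order-stable", {
  g <- generate_dataset(synth_spec(n_species = 4, genes_per_aa = c(1L, 1L),
                                   seed = 5))
  al1 <- prepare_records(g$records)
  shuffled <- g$records[rev(seq_len(nrow(g$records))), ]
  al2 <- prepare_records(shuffled)
  expect_equal(al2$slots[rownames(al1$slots), ], al1$slots)
})

test_that("extract_features reads the named slots and refuses anticodon labels", {
  good <- identity_body("GUG")
  recs <- trna_records(record_id = c("a", "b"), species_id = "sp1",
                       amino_acid = "His", anticodon = "GUG",
                       sequence = good, anticodon_start = 33L)
  al <- prepare_records(recs)
  tab <- extract_features(al, "N73")
  expect_equal(dim(tab$x), c(2L, 1L))
  expect_equal(unname(tab$x[, "N73"]), rep(substr(good, 73, 73), 2))
  expect_equal(tab$labels, c("His", "His"))
  expect_error(extract_features(al, c("N73", "N35")), "anticodon")
})

test_that("the default candidate set has 43 labels outside the anticodon region", {
  cand <- default_candidate_positions()
  expect_length(cand, 43L)
  expect_true(all(!cand %in% c("N34", "N35", "N36")))
  nums <- as.integer(sub("N", "", cand))
  expect_true(all(nums %in% c(1:7, 8:26, 49:65, 66:73)))
  expect_false(any(c("N8", "N14", "N54") %in% cand))
})

test_that("synthetic generation plus alignment recovers the true slots when indel-free", {
  g <- generate_dataset(synth_spec(n_species = 4, genes_per_aa = c(1L, 2L),
                                   intron_rate = 0.5, seed = 9))
  al <- prepare_records(g$records)
  expect_equal(nrow(al$rejects), 0L)
  # every aligned row is gap-free on N1..N73 and matches the planted code
  expect_false(any(al$slots[, 1:73] == "-"))
  tab <- extract_features(al)
  codes <- extract_morna_codes(tab, g$truth$planted$position)
  truth <- g$truth$codes
  key <- paste(al$meta$species_id, al$meta$amino_acid)
  expect_equal(unname(codes),
               truth$code[match(key, paste(truth$species, truth$amino_acid))])
})
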
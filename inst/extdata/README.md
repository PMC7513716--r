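# Packaged reference tables

All files are UTF-8, tab-separated, `.` decimal point, empty cell =
missing.

## table2_variants.tsv — variant matrix (the typing reference)

Columns: `pos` (1-based position on the H1 reference coordinate system;
`start-end` for blocks), `kind` (`SNP`, `Sub`, `Ins`), then one state
column per haplotype. SNP states are single bases; `Sub` states are block
lengths in bp; `Ins` states are the inserted sequence (or its length when
only the length is known), empty when absent.

Example row: `1220	SNP	C	T	C	...` — the single SNP separating H1
from H2.

## table1_haplotypes.tsv — segment compositions and carrier counts

Columns: `haplotype`, `atp6`, `fs`, `ncs`, `orf79` (empty = absent),
`n_rufipogon`, `n_sativa`. Totals: 44 wild + 30 cultivated carriers.

## table3_regions.tsv — regional survey summary

One row per survey region (SA-I, SA-II, EA, SEA): accessions sampled,
structure/orf79 carriers, haplotype and allele counts.

## region_haplotype_counts.tsv — carriers of each haplotype per region

Wild-rice carrier counts of each structure haplotype in the four survey
regions, reconstructed from the published regional summaries (row sums
equal the wild-rice counts of table1; column sums equal the carrier
counts of table3). Used by the origin scan's intersection filter.
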
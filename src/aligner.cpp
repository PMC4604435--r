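#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Brute-force end-to-end (ungapped) placement of short reads on a small
// reference. For each read, every offset on both strands of every
// chromosome is scored by Hamming distance (early exit past the mismatch
// cap); only placements in the minimal-mismatch stratum are reported, and
// reads whose stratum exceeds max_loci are suppressed entirely.

static inline char comp(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
  }
}

// [[Rcpp::export(name = ".align_seqs_cpp")]]
List align_seqs_cpp(CharacterVector reads, CharacterVector chrom_seqs,
                    int max_mismatches, int max_loci) {
  int n_chrom = chrom_seqs.size();
  std::vector<std::string> chroms(n_chrom);
  for (int c = 0; c < n_chrom; ++c) chroms[c] = as<std::string>(chrom_seqs[c]);

  std::vector<int> out_read, out_chrom, out_pos, out_mm, out_nh;
  std::vector<int> out_strand; // 0 = +, 1 = -
  std::vector<int> hit_seen, hit_chrom, hit_pos, hit_mm, hit_strand;

  int n_reads = reads.size();
  for (int r = 0; r < n_reads; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int w = fwd.size();
    std::string rev(w, 'N');
    for (int i = 0; i < w; ++i) rev[w - 1 - i] = comp(fwd[i]);

    hit_chrom.clear(); hit_pos.clear(); hit_mm.clear(); hit_strand.clear();
    int best = max_mismatches + 1;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = strand == 0 ? fwd : rev;
      for (int c = 0; c < n_chrom; ++c) {
        const std::string& ref = chroms[c];
        int L = (int)ref.size();
        for (int p = 0; p + w <= L; ++p) {
          int mm = 0;
          for (int i = 0; i < w; ++i) {
            if (q[i] != ref[p + i]) {
              if (++mm > max_mismatches) break;
            }
          }
          if (mm <= max_mismatches) {
            hit_chrom.push_back(c);
            hit_pos.push_back(p + 1);
            hit_mm.push_back(mm);
            hit_strand.push_back(strand);
            if (mm < best) best = mm;
          }
        }
      }
    }

    // minimal-mismatch stratum only
    int n_best = 0;
    for (size_t k = 0; k < hit_mm.size(); ++k)
      if (hit_mm[k] == best) ++n_best;
    if (n_best == 0 || n_best > max_loci) continue;

    for (size_t k = 0; k < hit_mm.size(); ++k) {
      if (hit_mm[k] != best) continue;
      out_read.push_back(r + 1);
      out_chrom.push_back(hit_chrom[k] + 1);
      out_pos.push_back(hit_pos[k]);
      out_strand.push_back(hit_strand[k]);
      out_mm.push_back(hit_mm[k]);
      out_nh.push_back(n_best);
    }
  }

  return List::create(_["read"] = wrap(out_read),
                      _["chrom"] = wrap(out_chrom),
                      _["pos"] = wrap(out_pos),
                      _["strand"] = wrap(out_strand),
                      _["mismatches"] = wrap(out_mm),
                      _["nh"] = wrap(out_nh));
}
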
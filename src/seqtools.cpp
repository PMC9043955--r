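#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp_base(r[i]);
  return r;
}

static inline bool valid_kmer(const char *p, int k) {
  for (int i = 0; i < k; ++i) {
    char c = p[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
  }
  return true;
}

//' Count strand-canonical k-mers over a set of reads.
//'
//' A k-mer and its reverse complement are collapsed onto the
//' lexicographically smaller of the two. Windows containing characters
//' outside {A,C,G,T} are skipped.
//'
//' @noRd
// [[Rcpp::export]]
List cpp_kmer_count(CharacterVector reads, int k) {
  std::unordered_map<std::string, int> tab;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    if ((int)s.size() < k) continue;
    for (size_t j = 0; j + k <= s.size(); ++j) {
      if (!valid_kmer(s.c_str() + j, k)) continue;
      std::string km = s.substr(j, k);
      std::string rc = revcomp_str(km);
      const std::string &canon = (rc < km) ? rc : km;
      tab[canon] += 1;
    }
  }
  CharacterVector kms(tab.size());
  IntegerVector cnts(tab.size());
  R_xlen_t idx = 0;
  for (auto &kv : tab) {
    kms[idx] = kv.first;
    cnts[idx] = kv.second;
    ++idx;
  }
  return List::create(_["kmer"] = kms, _["count"] = cnts);
}

static inline int mismatches_capped(const char *a, const char *b, int n, int cap) {
  int mm = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] != b[i]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

//' Mismatch-only (ungapped) mapping of reads against references.
//'
//' Each read is slid over every reference on both strands; the best
//' placement per (read, reference) is recorded. Mismatch counts are capped
//' at max_mm + 1 (placements worse than max_mm are never used downstream).
//' Returns per-read x per-reference matrices of best mismatch count,
//' 1-based best start position on the forward reference, and strand
//' (1 = forward, -1 = reverse, 0 = unplaced).
//'
//' @noRd
// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector refs, int max_mm) {
  int nr = reads.size(), nf = refs.size();
  std::vector<std::string> fw(nf), rv(nf);
  for (int j = 0; j < nf; ++j) {
    fw[j] = as<std::string>(refs[j]);
    rv[j] = revcomp_str(fw[j]);
  }
  IntegerMatrix mm_out(nr, nf), pos_out(nr, nf), strand_out(nr, nf);
  int cap = max_mm;
  for (int i = 0; i < nr; ++i) {
    std::string rd = as<std::string>(reads[i]);
    int L = rd.size();
    for (int j = 0; j < nf; ++j) {
      int RL = fw[j].size();
      int best = cap + 1, best_pos = 0, best_strand = 0;
      if (L <= RL) {
        for (int p = 0; p + L <= RL; ++p) {
          int mm = mismatches_capped(rd.c_str(), fw[j].c_str() + p, L, best - 1);
          if (mm < best) { best = mm; best_pos = p + 1; best_strand = 1; if (best == 0) break; }
        }
        if (best > 0) {
          for (int p = 0; p + L <= RL; ++p) {
            int mm = mismatches_capped(rd.c_str(), rv[j].c_str() + p, L, best - 1);
            if (mm < best) {
              best = mm;
              // convert to forward coordinates: reverse position p covers
              // forward [RL - p - L, RL - p - 1] (0-based)
              best_pos = RL - p - L + 1;
              best_strand = -1;
              if (best == 0) break;
            }
          }
        }
      }
      mm_out(i, j) = best;
      pos_out(i, j) = best_pos;
      strand_out(i, j) = best_strand;
    }
  }
  return List::create(_["mismatch"] = mm_out, _["pos"] = pos_out,
                      _["strand"] = strand_out);
}

//' All ungapped occurrences of a pattern in a subject, both strands,
//' with at most max_mm mismatches. 1-based start positions on the
//' forward subject; strand "+"/"-".
//'
//' @noRd
// [[Rcpp::export]]
DataFrame cpp_anchor_scan(std::string subject, std::string pattern, int max_mm) {
  std::vector<int> pos;
  std::vector<int> mms;
  std::vector<std::string> strands;
  int n = subject.size(), m = pattern.size();
  std::string rc = revcomp_str(pattern);
  for (int p = 0; p + m <= n; ++p) {
    int mm = mismatches_capped(subject.c_str() + p, pattern.c_str(), m, max_mm);
    if (mm <= max_mm) {
      pos.push_back(p + 1); mms.push_back(mm); strands.push_back("+");
    } else {
      mm = mismatches_capped(subject.c_str() + p, rc.c_str(), m, max_mm);
      if (mm <= max_mm) {
        pos.push_back(p + 1); mms.push_back(mm); strands.push_back("-");
      }
    }
  }
  return DataFrame::create(_["pos"] = pos, _["strand"] = strands,
                           _["mismatches"] = mms,
                           _["stringsAsFactors"] = false);
}

//' Depth-first enumeration of candidate repeat-unit cycles seed -> seed
//' through the pruned k-mer graph. `oriented_kmers` holds every retained
//' k-mer in both orientations; at graph branch points an extension is only
//' followed if the trailing `w_sup`-window of the grown path occurs in the
//' read-support window set. Paths longer than max_len are abandoned.
//'
//' @noRd
// [[Rcpp::export]]
CharacterVector cpp_enumerate_units(CharacterVector oriented_kmers,
                                    CharacterVector seeds, int k,
                                    CharacterVector windows, int w_sup,
                                    int max_len, int max_candidates) {
  std::unordered_set<std::string> kset;
  for (R_xlen_t i = 0; i < oriented_kmers.size(); ++i)
    kset.insert(as<std::string>(oriented_kmers[i]));
  std::unordered_set<std::string> wset;
  for (R_xlen_t i = 0; i < windows.size(); ++i)
    wset.insert(as<std::string>(windows[i]));
  // every seed (the CDS-start k-mer and its variants present in the
  // graph) both starts a traversal and terminates any traversal, so each
  // candidate spans exactly one repeat unit
  std::unordered_set<std::string> terminal;
  for (R_xlen_t i = 0; i < seeds.size(); ++i)
    terminal.insert(as<std::string>(seeds[i]));

  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  std::unordered_set<std::string> seen_units;
  std::vector<std::string> out;
  std::vector<std::string> stack;
  for (R_xlen_t i = 0; i < seeds.size(); ++i)
    stack.push_back(as<std::string>(seeds[i]));
  long steps = 0;
  while (!stack.empty()) {
    std::string path = std::move(stack.back());
    stack.pop_back();
    std::string core = path.substr(path.size() - k + 1);
    std::string nexts;
    for (int b = 0; b < 4; ++b) {
      if (kset.count(core + BASES[b])) nexts.push_back(BASES[b]);
    }
    bool branching = nexts.size() > 1;
    for (size_t b = 0; b < nexts.size(); ++b) {
      std::string newpath = path + nexts[b];
      if (branching && (int)newpath.size() >= w_sup) {
        if (!wset.count(newpath.substr(newpath.size() - w_sup))) continue;
      }
      std::string nk = newpath.substr(newpath.size() - k);
      if (terminal.count(nk)) {
        if ((int)newpath.size() - 2 * k >= 0) {
          std::string unit = newpath.substr(0, newpath.size() - k);
          if (seen_units.insert(unit).second) {
            out.push_back(unit);
            if ((int)out.size() > max_candidates)
              stop("candidate repeat-unit paths exceed max_candidates");
          }
        }
        continue;
      }
      if ((int)newpath.size() - k >= max_len) continue;
      stack.push_back(std::move(newpath));
    }
    if (++steps > 20000000L) stop("path enumeration did not terminate");
  }
  return wrap(out);
}

//' Subset of k-mers within a Hamming distance of a pattern (same length).
//'
//' @noRd
// [[Rcpp::export]]
CharacterVector cpp_hamming_neighbors(CharacterVector kmers,
                                      std::string pattern, int max_mm) {
  std::vector<std::string> out;
  int k = pattern.size();
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != k) continue;
    if (mismatches_capped(s.c_str(), pattern.c_str(), k, max_mm) <= max_mm)
      out.push_back(s);
  }
  return wrap(out);
}

//' Canonical k-mer multisets of a batch of circular units, as sparse
//' triplets over a shared k-mer dictionary. Each unit is wrapped by k-1
//' bases so the junction k-mers are included.
//'
//' @noRd
// [[Rcpp::export]]
List cpp_units_kmer_triplets(CharacterVector units, int k) {
  std::unordered_map<std::string, int> dict;   // kmer -> 1-based index
  std::vector<std::string> dict_names;
  std::vector<int> ti, tj;
  std::vector<double> tx;
  for (R_xlen_t u = 0; u < units.size(); ++u) {
    std::string s = as<std::string>(units[u]);
    s += s.substr(0, k - 1);
    std::unordered_map<int, int> counts;
    for (size_t j = 0; j + k <= s.size(); ++j) {
      if (!valid_kmer(s.c_str() + j, k)) continue;
      std::string km = s.substr(j, k);
      std::string rc = revcomp_str(km);
      const std::string &canon = (rc < km) ? rc : km;
      auto it = dict.find(canon);
      int idx;
      if (it == dict.end()) {
        idx = dict.size() + 1;
        dict[canon] = idx;
        dict_names.push_back(canon);
      } else {
        idx = it->second;
      }
      counts[idx] += 1;
    }
    for (auto &kv : counts) {
      ti.push_back(kv.first);
      tj.push_back(u + 1);
      tx.push_back(kv.second);
    }
  }
  return List::create(_["i"] = wrap(ti), _["j"] = wrap(tj),
                      _["x"] = wrap(tx), _["kmers"] = wrap(dict_names));
}

//' All substrings of length w of the given sequences (used to build the
//' read-support window index during graph path resolution). Windows seen
//' fewer than min_count times are dropped: a single sequencing error can
//' forge a chimeric junction window, but true junctions are covered many
//' times over.
//'
//' @noRd
// [[Rcpp::export]]
CharacterVector cpp_all_windows(CharacterVector seqs, int w,
                                int min_count = 1) {
  std::unordered_map<std::string, int> tab;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < w) continue;
    for (size_t j = 0; j + w <= s.size(); ++j) tab[s.substr(j, w)] += 1;
  }
  std::vector<std::string> out;
  for (auto &kv : tab) {
    if (kv.second >= min_count) out.push_back(kv.first);
  }
  return wrap(out);
}
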
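LOCUS       SYNPHG01             4198 bp    DNA     circular PHG 01-JAN-2026
DEFINITION  Synthetic phage-like test record (computer generated, not a real
            organism).
ACCESSION   SYNPHG01
VERSION     SYNPHG01.1
SOURCE      synthetic construct
FEATURES             Location/Qualifiers
     source          1..4198
                     /organism="synthetic construct"
     gene            101..3214
                     /locus_tag="synorf001"
     CDS             101..3214
                     /locus_tag="synorf001"
                     /product="synthetic tail-spike-sized protein"
                     /translation="MTFALEVTRHEFQYVRDKEFPFYCIDALMRIEEVPFECVDTVGG
                     CYDCGLIFATHEPLKNYKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSMLLAW
                     TQQRGRMFSTTVCGGGYRCLNKACCMQCCLFLTTFDQQAFDPMYTYEYMTKTPTYATA
                     CISDFPNAWFRGSLHKKDVRRYSAGMKYPFMRCGAQSTMVCLEYRHTFYVKMGLKWKM
                     WELTNGRKLVHQNWLFCDCQSEGYYMAQAEPGNHNFVHPCDARYMKLHWVNLKWRQDY
                     LCTVWQTLFPVWWLSCEHAQYWNWGNLHWCGKMGFQLRAKLTNAMEDGFLYCEYKQQD
                     VLAIYFGQEKISNLQMCSQRTGWLPGAMPLPRTRIEGLYSNSWDHDLLHWPLQMPDLW
                     CHYMMAGLKNPVRAMIPQCGPDPSWSPPIPGGIFKLMAREHMLIDPYSIDKSMPHVHF
                     YVHTDSIWVLRNDYSLCIAPHMMPFCRFQFTVTVHPCNDYIYQAQVCFLNDVVVRAIW
                     IYWCYWMRVILCETNYWHKWMMNTCYHTEPWATECIDPCEKMLQAAQYMKWFCKDNCS
                     VTYIIWRGDAREKAMGYQKGNTMKVMWAMTTIMVAGCQFAVERHQLDHFGFVKDDKPH
                     LTCYTNGWLSALHCEYIRQTFTTSYGDQKNKQDEDHAFEINNNRKDDKHNPTRRYDPW
                     CFKVAEVFDLHQLLKHGYIFWYMTHLNEYDASFWTMAAVDFHGSPAWVLQLCSKTCRI
                     DCTDMFADQGSLIKDCGCSKFTNYEGCDVTVMIHYAWSIYVLLWPNIGHHFAWMCVLG
                     ENGTQAMYWFDPWVYQCAQHRGNYMLTLWLKIWHSISMLYVSIFVRCALKATPGNWAM
                     SQWFIWSNRHARIGMCAYFFMTTTWPVLDTLAMPQPHIEQFYWQWRSDCGHLPLLDYT
                     VTLLIPIYFTKIWPANAGWPWFPQQYNYIMQCQLCLDCLRWNVVMKIKIDILLCMLSY
                     CLQWESRMWLCFWMVYMLFPLTDQLCFNRGAPKQNVHSNNGWVCIARVQAGWEAAARV
                     MALYKFG"
     CDS             complement(3365..3727)
                     /locus_tag="synorf002"
                     /product="synthetic protein without stored translation"
     tRNA            3808..3835
                     /locus_tag="syntrna01"
                     /product="tRNA-Xxx"
     CDS             3896..4078
                     /locus_tag="synorf003"
                     /translation="MAAMQAYDDTWWQAGGQTYYIKEHERHRSPTRAWISQMLRVCIS
                     FQHFNGTSFGFAYVWA"
ORIGIN
        1 gtggaggcgc atattaagag tatactatcg aggaattgct ggatggatac tatatttcca
       61 aaacagcact gtatttgacg ccgctatggc cctcgtgggt atgacattcg cactagaagt
      121 aacccgtcac gaatttcaat atgttcgcga caaggaattt cccttttact gcatagacgc
      181 tcttatgcgt atagaagaag taccttttga gtgcgttgat acagttggag gttgttatga
      241 ctgcggactt atttttgcta ctcacgagcc tttaaaaaac tataagatgg atagttttca
      301 gttttgcgtt actgtttttc agataatcga agaacacttg gttccatggt cgacgaataa
      361 aatgagtata ggtgccccgc agtttaagtc tatgttactc gcttggacac aacagcgagg
      421 cagaatgttt tccacgaccg tgtgtggtgg tggataccgg tgcttaaata aagcctgttg
      481 tatgcagtgc tgcctcttcc tcacgacgtt tgaccagcaa gctttcgacc ctatgtacac
      541 ctatgaatac atgactaaaa cccccactta cgcaactgca tgtatatcgg actttccgaa
      601 cgcctggttc cgggggtccc ttcacaaaaa agatgtacgg agatattctg cgggaatgaa
      661 ataccctttc atgcggtgtg gcgcacaaag caccatggtc tgcctggagt acagacacac
      721 attctacgtc aaaatggggc taaagtggaa aatgtgggaa ctaacaaacg ggcgcaaact
      781 tgtgcatcaa aattggctct tttgcgactg tcagtccgaa ggttactaca tggcacaagc
      841 agaacctggg aaccacaact tcgttcatcc atgcgacgct aggtatatga aactccattg
      901 ggtcaatctg aaatggcggc aggactacct ctgtacagtc tggcagacac ttttccctgt
      961 gtggtggctc tcctgcgagc acgcccagta ctggaattgg ggcaacctcc attggtgtgg
     1021 gaagatgggt tttcagctac gagccaaact gacaaacgcg atggaagacg gcttccttta
     1081 ctgcgagtat aaacagcaag atgtactggc tatttatttt ggacaagaga agatatctaa
     1141 cttgcaaatg tgctcccagc gaaccggatg gctcccgggc gctatgccat tgcctcgaac
     1201 ccggattgaa ggactctatt cgaacagttg ggaccatgat ctcttgcact ggccgttgca
     1261 gatgcccgat ctttggtgcc actatatgat ggcgggtctg aaaaacccgg ttcgcgccat
     1321 gatcccacaa tgcggtcctg atccctcttg gtctccgccg atacccgggg gaatctttaa
     1381 acttatggcg cgtgagcaca tgctcattga tccatactca atcgacaaaa gtatgccgca
     1441 cgtacatttt tacgtgcata cagactcaat atgggtcctt agaaacgact atagcctctg
     1501 tattgcaccg catatgatgc ccttctgccg attccagttc accgttacag tgcatccgtg
     1561 taacgactat atttaccaag cccaagtgtg ttttttaaac gacgtcgttg tcagggctat
     1621 atggatatat tggtgttatt ggatgcgggt tatactctgt gaaaccaatt attggcacaa
     1681 gtggatgatg aatacgtgtt atcacaccga accatgggct acggaatgta tagatccgtg
     1741 tgaaaagatg ctacaagcag cacaatatat gaagtggttt tgcaaggata attgctcagt
     1801 tacgtacata atatggcgag gagacgcacg ggaaaaagct atggggtacc agaagggtaa
     1861 tactatgaaa gtaatgtggg cgatgacaac aattatggta gccgggtgtc aatttgcagt
     1921 cgagcggcat caacttgatc atttcggttt tgtaaaagac gacaaacctc acttaacatg
     1981 ctatacgaat ggttggttga gcgcattaca ttgtgaatac atccggcaaa cgttcacgac
     2041 gtcctatggg gaccaaaaaa ataagcagga tgaagaccat gcctttgaga ttaacaataa
     2101 caggaaagac gataagcaca atccgactcg ccgatacgac ccttggtgct ttaaggtagc
     2161 tgaagtgttc gacctccacc agctcttgaa gcatgggtac atattttggt acatgactca
     2221 tttgaatgaa tatgatgctt cgttctggac catggcggct gtcgattttc atggatcgcc
     2281 ggcttgggtt ctccagctgt gctccaagac ctgccggatt gactgtacag atatgtttgc
     2341 tgatcaagga tctcttatta aagactgcgg gtgctccaag ttcacgaatt acgagggctg
     2401 tgatgtaact gtcatgatcc attacgcttg gtcgatttac gtgctactct ggcctaacat
     2461 cggacatcat ttcgcttgga tgtgtgttct aggagaaaac ggaacacaag ctatgtactg
     2521 gttcgaccct tgggtgtatc agtgcgcgca acatagggga aattacatgc tgaccttatg
     2581 gctcaagatc tggcactcta tctcaatgtt gtacgtatca atatttgtca gatgcgcact
     2641 gaaagcaacc cccggcaact gggccatgtc gcagtggttc atctggagca ataggcacgc
     2701 ccgaataggc atgtgtgcat acttttttat gacaacaacg tggccagttc tcgacactct
     2761 cgccatgcct cagccacaca ttgaacagtt ttactggcaa tggcgaagcg actgtggcca
     2821 cttgcctctg ttggactaca cagttaccct tttaattccc atttatttta ccaagatctg
     2881 gccggcgaac gctggttggc catggttccc acaacaatac aactatatta tgcagtgcca
     2941 actttgtcta gattgcttgc ggtggaatgt cgttatgaaa atcaaaatag acatattgct
     3001 atgtatgttg tcgtattgtc ttcagtggga gagcaggatg tggttatgct tttggatggt
     3061 ctatatgtta tttccattaa ccgatcaact atgttttaac cggggagccc caaagcagaa
     3121 tgttcattct aacaatggct gggtatgtat agcccgggtt caagctggtt gggaagcagc
     3181 cgcgcgggta atggcgcttt acaaattcgg ttaagacatg ctgggttagc tagccgggca
     3241 acaactctta gcgttgagtc gggctcagag ttgcacccgt tggctgggtt aaatatatca
     3301 cacggcaagc gatgcgtcat gtaataggtg cggaactcca gattggcgat gtgcaattac
     3361 tgtgttactg agataggaac gggtctagcg ccatacctag tccgtagtct ctattccgat
     3421 ctacatcgta gttatacaag tacgtcccgt gatcaagctc attgaaaggt ttatcgattc
     3481 gccactcggg gctaaacata acatcatgcg atagatgcat ctctgtgtcc aaggtcgcag
     3541 tagtcgagcg attgtaccgc gccgggttac attccgagag cggatgtaca ttaaattctc
     3601 ctatgaagct ttgcataaaa tcttgaaaca ttttggcgac aggtgataaa tcgtaaggcc
     3661 atcttcttac ccacagcatc cgccgttgat gaatgataag gtttgtgctg attccccaaa
     3721 acatcatcga cttgtcatat ctacagggga ctccagaata tcacgtactt cccaataccc
     3781 aatatcttgc aaccaagcgt ttaatcaggg gcccttagct cagttggtag agcgccctgt
     3841 taaattgtgt agagtagtaa gcagattact gcggagagag agcgcgaatc tatacatggc
     3901 ggctatgcag gcctatgatg atacgtggtg gcaagcaggc ggccagactt attatattaa
     3961 agagcacgag cgtcaccggt ccccgacccg tgcttggatc agccagatgc tacgagtgtg
     4021 catttcgttc caacacttca acggaacatc gtttggtttt gcctacgttt gggcctaata
     4081 cgctccgtct ggttaccgtt gcctggtaag aatgactacg gcctagaatg ggtccacacc
     4141 ctgcctccta aaattgcact gagcagcaga gcaacgagtg acaaagctgg gagccccc
//
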
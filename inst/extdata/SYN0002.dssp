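==== Secondary Structure Definition, toy generator ====
  120  1  0  0  0    TOTAL NUMBER OF RESIDUES
  #  RESIDUE AA STRUCTURE BP1 BP2  ACC
    1    1 A A  H
    2    2 A E  H
    3    3 A Q  H
    4    4 A N  H
    5    5 A G  H
    6    6 A Q  H
    7    7 A R  H
    8    8 A A  H
    9    9 A M  E
   10   10 A T  E
   11   11 A S  E
   12   12 A E  H
   13   13 A S  H
   14   14 A I  H
   15   15 A F  H
   16   16 A H  T
   17   17 A K  T
   18   18 A R   
   19   19 A D   
   20   20 A H   
   21   21 A G   
   22   22 A K   
   23   23 A Q   
   24   24 A S   
   25   25 A N  S
   26   26 A S  S
   27   27 A Q  S
   28   28 A G  S
   29   29 A N  S
   30   30 A V  S
   31   31 A L  S
   32   32 A P   
   33   33 A S   
   34   34 A Y   
   35   35 A R  T
   36   36 A K  T
   37   37 A L  T
   38   38 A Y  T
   39   39 A K  T
   40   40 A Q  T
   41   41 A S  T
   42   42 A C  T
   43   43 A V  T
   44   44 A K  T
   45   45 A P  T
   46   46 A H  T
   47   47 A L  T
   48   48 A V  T
   49   49 A Y  T
   50   50 A N  H
   51   51 A M  H
   52   52 A R  H
   53   53 A H  H
   54   54 A L  H
   55   55 A L  H
   56   56 A R  H
   57   57 A T  H
   58   58 A K  H
   59   59 A P  H
   60   60 A I  H
   61   61 A F  H
   62   62 A P  H
   63   63 A G  H
   64   64 A M  H
   65   65 A F  H
   66   66 A Y  H
   67   67 A P  H
   68   68 A P  H
   69   69 A V  H
   70   70 A A  H
   71   71 A C  H
   72   72 A L  H
   73   73 A G  H
   74   74 A S  H
   75   75 A L  H
   76   76 A Q  H
   77   77 A G  H
   78   78 A L  H
   79   79 A V  H
   80   80 A L  H
   81   81 A R  H
   82   82 A D  H
   83   83 A V  H
   84   84 A E  H
   85   85 A R  E
   86   86 A I  E
   87   87 A G  E
   88   88 A A  E
   89   89 A S  E
   90   90 A D  E
   91   91 A T  E
   92   92 A I  E
   93   93 A Q  E
   94   94 A T  E
   95   95 A I  E
   96   96 A Q  E
   97   97 A D  E
   98   98 A A  H
   99   99 A P  H
  100  100 A I  H
  101  101 A L  H
  102  102 A Q  H
  103  103 A P  H
  104  104 A K  H
  105  105 A T  H
  106  106 A M  H
  107  107 A K  H
  108  108 A M  H
  109  109 A F  E
  110  110 A M  E
  111  111 A F   
  112  112 A P   
  113  113 A Y  S
  114  114 A L  S
  115  115 A A  S
  116  116 A T  S
  117  117 A S  S
  118  118 A E  S
  119  119 A L  S
  120  120 A C  S
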
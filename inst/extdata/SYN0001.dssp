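==== Secondary Structure Definition, toy generator ====
  120  1  0  0  0    TOTAL NUMBER OF RESIDUES
  #  RESIDUE AA STRUCTURE BP1 BP2  ACC
    1    1 A V   
    2    2 A Y   
    3    3 A P  H
    4    4 A L  H
    5    5 A G  S
    6    6 A Q  S
    7    7 A Y  S
    8    8 A P  S
    9    9 A P  S
   10   10 A R  S
   11   11 A S  S
   12   12 A I  H
   13   13 A K  H
   14   14 A C  H
   15   15 A K  H
   16   16 A K  H
   17   17 A L  H
   18   18 A T  H
   19   19 A A   
   20   20 A R   
   21   21 A H   
   22   22 A D   
   23   23 A P   
   24   24 A G   
   25   25 A I   
   26   26 A G   
   27   27 A E   
   28   28 A T   
   29   29 A L   
   30   30 A M   
   31   31 A A  T
   32   32 A L  T
   33   33 A Q  T
   34   34 A R  T
   35   35 A Y  T
   36   36 A I   
   37   37 A C   
   38   38 A D   
   39   39 A F   
   40   40 A G  T
   41   41 A R  T
   42   42 A V  T
   43   43 A E  T
   44   44 A R  T
   45   45 A I  T
   46   46 A D  T
   47   47 A E  T
   48   48 A Q  T
   49   49 A N  T
   50   50 A V  T
   51   51 A A  T
   52   52 A T  T
   53   53 A V  T
   54   54 A T  T
   55   55 A E  T
   56   56 A K  T
   57   57 A T  T
   58   58 A Q  T
   59   59 A L  T
   60   60 A D  T
   61   61 A S  T
   62   62 A S  T
   63   63 A L  T
   64   64 A L  T
   65   65 A N  T
   66   66 A S  T
   67   67 A S  T
   68   68 A Y  T
   69   69 A V  T
   70   70 A N  T
   71   71 A E  T
   72   72 A W  T
   73   73 A P  H
   74   74 A G  E
   75   75 A G  E
   76   76 A Y  E
   77   77 A T  E
   78   78 A A  T
   79   79 A G  T
   80   80 A K  T
   81   81 A L  T
   82   82 A I  T
   83   83 A S  T
   84   84 A E  T
   85   85 A P  H
   86   86 A I  H
   87   87 A G  H
   88   88 A G  H
   89   89 A D  H
   90   90 A T  H
   91   91 A H  H
   92   92 A A   
   93   93 A G   
   94   94 A W   
   95   95 A E   
   96   96 A S  I
   97   97 A P  I
   98   98 A K  I
   99   99 A V  I
  100  100 A V  I
  101  101 A A  I
  102  102 A Q  I
  103  103 A L  I
  104  104 A A  I
  105  105 A C  H
  106  106 A D  H
  107  107 A G  H
  108  108 A G  H
  109  109 A V  H
  110  110 A A  T
  111  111 A S  T
  112  112 A P  T
  113  113 A D  T
  114  114 A D  T
  115  115 A V  T
  116  116 A V  T
  117  117 A N  T
  118  118 A P  T
  119  119 A R  T
  120  120 A C  T
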
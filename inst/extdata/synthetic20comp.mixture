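ClassName = Dirichlet
Order = A C D E F G H I K L M N P Q R S T V W Y
NumDistr= 20
Background=        0.05        0.05        0.05        0.05        0.05        0.05        0.05        0.05        0.05        0.05        0.05        0.05        0.05        0.05        0.05        0.05        0.05        0.05        0.05        0.05
Number= 0
Mixture=        0.05
Alpha=           2        1.62        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02
Number= 1
Mixture=        0.05
Alpha=           2        0.02        1.62        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02
Number= 2
Mixture=        0.05
Alpha=           2        0.02        0.02        1.62        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02
Number= 3
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        1.62        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02
Number= 4
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        0.02        1.62        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02
Number= 5
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        0.02        0.02        1.62        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02
Number= 6
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        0.02        0.02        0.02        1.62        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02
Number= 7
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        0.02        0.02        0.02        0.02        1.62        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02
Number= 8
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        1.62        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02
Number= 9
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        1.62        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02
Number= 10
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        1.62        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02
Number= 11
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        1.62        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02
Number= 12
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        1.62        0.02        0.02        0.02        0.02        0.02        0.02        0.02
Number= 13
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        1.62        0.02        0.02        0.02        0.02        0.02        0.02
Number= 14
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        1.62        0.02        0.02        0.02        0.02        0.02
Number= 15
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        1.62        0.02        0.02        0.02        0.02
Number= 16
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        1.62        0.02        0.02        0.02
Number= 17
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        1.62        0.02        0.02
Number= 18
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        1.62        0.02
Number= 19
Mixture=        0.05
Alpha=           2        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        0.02        1.62
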
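>query
HTRSCMFYVAHWVIFAMCARSCYERSLKAWGEIRFSSPTMFYLRTWKVHSHNNNANVVSG
PYDLIMLKHEQWPPRIHHCLGRTQALHSGTHCLGCPMCDIYAKCDSGWLGNAGMITYGNR
FNVKMTKDWIHEDFYDRCRGAKIEQGDKEMEKAYAGLSELRDTMICNVPVGWSPCPNFWK
FNLPRMDDMLKYLTLTCWNTHMEHVIFWRIHNYIKVHTEKIRHFCKVRLPVVAHLHEWLK
>sf1_s2
TNQQGEKPLQVNLEKKHAPRDHGLEVKKTAGEIRFSAVTMHYLRTWKVHSHNRNACVVSG
ACFTWIRVYFTLEEIARMQDGWQLKLNEHPAMEMDEPEEFHLSCGGYPDCKWMLPVTCAQ
NKPQMYSQAEHEDFADRCRAPKIENGDKEMEKAYAGNSELVSDSTQMDILVKYFEQYAWE
KEPQDNQDVCHGHYWNGVHEHYDNPKLNFFQWNVDLDPGAEMTNGISKHKTEVDCNINSN
>sf1_s3
YERTMNPCKEMDEWVRDCNMYWFQDRSMTFVEIRFSAVTMHMLRTWKVHSYENNACVVSG
YCATDACIDCWPGIANMIISSPACCGMNPMIRRGCIPVETGQHMIEYNPFTYQYSPASWH
LYILHRSMDLHEDFYDRCRAPKIENGEKIMEKAYAGNSELDNHLQFMAYHNGVEPPMDLQ
WEAPWRWMSHSWAPTVPNHANNRNYCDGWFIHWTKHLKRIKCFYDGYTKIAWIGPDGIGR
>sf1_s4
QCKENAAMPYSILANWAVQKLKIYFIHAAYGQIRWSAVTMDYLRTTEVHSHCNNDCVVSG
TEQMCVQSVVFLIWCQSAKHSLSNEWKDMSQFHIGFMKCSMSKSAIRWHAESNRIKFWDW
ILYWISTCEVHEDFYPRCRAPKIECGDKEMEKAYAGNSELCHHVDKAWGPHVLDFAVGIG
IDVIRFWTPKKRVTHDFIKGFDKWWLTNRSMCDNRCPMAKYGANWNFMRDVRLNKDNQCS
>sf1_s5
KPDLSQTCFCIQGAYTGFQIREMMLESVGYGEIRFSHVTMHYWRTWKVHSHNNIACVVHG
INDGAQEQWAKCVYNTNRCNVVTVERIVCCAEQVNNWWQARDSLTVFFPWEVNNTPMIGC
YKGQGMIRDFHGEFYDQCRAPKIENGDKEMEKAYAGNSELEISTRPLIPTPQNKQFIKAA
KARTCGFAGIFSYQTTSDTAKQFTLISNEIALDSYFPWAWVFQYVTYYLPDQENLMMFAR
>sf2_s1
GQCNVTFMGVEDQLSTTPHVRIDGFTDYKAGEIRFSAVTMHYLRTMKVHSHYNNECVVSG
WDPKELKAGETEGFTAGQMWFFPAFTNQCGKQPAAEWFMDKTELCWHLSVAIMWDPFSAA
DFQRHYATIDHEDFYDRCRAPKHENGLKQMEKAIAGNSELNAILKWEPQVWTRLYPHMVM
EEAGRYQKIWKHWYPMPHFYPFKWCFVAPGVVFQYTGWYDCKRRVCMTELYPVADPWMIW
>sf2_s2
GMCTRCARGYQMCAWSSLEHLMQQLSMARIAQNKQDPHPGLLMRFCWTISWFFWVVKCSH
GEVPLIMAVWHFEKWWYKMTNDHDMTKRSTWRRIQTWDNYGEISFYLFMQALQFRQEPAN
FCSCCTWAGWHEDFYDRCRAPKIENDDKGMEKWYAGNSKLQLIDASWVEWRVSFSFGKCP
QVLKDLAYPRAHGRIVGIYQWDDPIWSQGPDQIHAAHFMFLNMHKILYFWWFPCYREQCP
>sf2_s3
PKHGMRYKIQINMQEIIGQWDARIREAVMYGEVRFSAVKMHYLRTWKTHSHNNNACVPSG
RKIAQAIGLSFWEHHEPFQYYPQIGKEAIMQWRFIDFIYFWTYFSMSWDRSQQMRKTKSK
MYFSIDTRPLAEDFYDRCRAPKIENGKPEMEKMYAGNSMLIDHSRNAIFRPQMTDHCWVS
RVTGWTYIEECARRSDCWHIMISNEVKHEHCQSVIYEFLRPNSSRNDDFTQEDNRMPQPS
>sf2_s4
NKECFLPTHHMEAGDMHAYGLIMVAFCLSEGEIRFSAVTMHYLRTIKVHSHNNNACVVSG
PHMCALTRGHYYYDLYPNEKQPMRYRLYVLLQCYKNLANFNEWQNNWWYERVRVPMSYLP
TQGSAVYDLMHNDFYDRCRAPKIEQGDKEMEKAYAGNWELDTELQKRLCHKIFEGEYTCW
MEWYKYCMLCWYCHIPCPAGQQLHQQVQHFNECMQTNGFDGEEWKYMAYMIYSLWDRDNC
>sf2_s5
CQSIHKVDDMMMSSEMGEMTTNKEPEVSWCSEIRDSDVTMHYLRIWKVHSHNNNACVVSG
AEPIFFKEFYCNGIEIVQLRWYDAHFWGQCEKDKMNHPSRLWYRGQTNKGTDLFKGHDMG
MTPLRMNPHKHEDLYDRCRAPKIENGDKPMEVAYAGNSELQVIQCHESMSSHCLEDCRRA
QCFFDTCMAKVAKSTNWQCVGKESQPYKCMFPVHDPYSNHWFSWNRANTPEKYTAEDDSY
>sf3_s1
RFYDFCHGFAGYGRSCSWKPVYWDHDWAIAGEKRFSSVTMHYLRTWCVHSHNNNACVVSG
RDEYSYAVEMSWFDYPSDIFKQCQTTVWWYPFMGKACTSQCYFTNYSDWTEKGWFQLCEV
KCGPEKQGEKVNMFYDRCRAPKIENGDGEMEKAYAGSSELWDSSFQYTKQIKCYFCDNKT
VDAGLCAPFEIGNHAAIIQCEHPFENHNKTMGQYVSIYLHLRLVVSWNLLYYAPMYYNTT
>sf3_s2
TEEKRCYVQHNMHRVNDVGQDLEINGYSCHGEIRFSAVTMHYRRTGKVRSHNNNACVFSG
IEGHKPHGHSPFSFECAHPFQICVNQWKRNMVLCHPFWWGPAESMPYGEECVFPKYMYIE
GCQLCPTVSGCPDFYDRCRAPKIENLDKEMEKAYAGNSELFKTHKSICSNYGVIQKHWQE
ANKFWARYSMPYHELRPKPKRPSMDMHQFYHSAGSQCGMYPDYEWSCEGMVWVIQIFPQG
>sf3_s3
FCCIGNQYGNWCCGIDRDAEGHMLVTMYENGEIRFSAPTMHYLRCWKVHSHNPNACVVSG
HVVSCEQGSQDDDAYGGAVMCHGGVTTVADMNWRGHIWKNMMEIEEWTVTQKCESDLLTH
QRDDYELNEFHEDFYKRCRAPKIENGDKEMEKDYAGNSELKFQLGFCCILTPTLQDRRVG
VCICCKRIPLDIFMPDFWAASAVCMWCCYESNWYKVIQIYWNRDELYTWCSLRMNVQAEM
>sf3_s4
NPQPWMYLMAGEIECECHDACIYHCDDKKRGEIRFSAVTMLYLRTWKVHSHNNNAHVVSG
NHAKDNFPSHTKHEGQSHQFQLRHEYHATTYWRSQLPQMRFRYWQGKNLSVEHFQHVTWF
YSLCGCPSKEHEDFYQRCMAPKIENGDKYMDKAYAGNFELVPCIRWGYTSFWRKQWREFN
GPGNKEDDESADHAWQLGAVTKMTYQSRCYFVTFTSIHSWPNSMIPMHDTNCCWWMTAQQ
>sf3_s5
NQQETTWVQMWVAEMRGKPGAYHYGVIIMRGEIRFSAVKMHYLRTWKVKSHNNNACVVSG
QGEGHHPKPVKDGLPWGDNRSWQREVMEHGRGPFLSERQNAEVDMWTLNVDTIRRGAIRH
LGFLMLNEQVPLYRSHRRGPQFTVIYNETKEHGNYQDEVVTCDEWSHWKAANSRQDIVDG
ITMEIYKWSHWNQRWCMIVAWRACNGQVYYGYKFISTELWVEQLICNRQQQHSFTTHSMG
>unrelated1
WGGYILWTHGYGGRAHSVLKEEENFYMNDEGDAECAPQMFYKSHVPWAWYERWFIFPNFE
ASIVDQSRWKVMVHETFVEGSIDHQTNHFHPAWKCELLFVFHLPYSPFWCITAFGRMYTV
YHSCTQSSTTKDGTGNTSWQTKIYDTDRSKTHKKASAVPIAMSDTNGNFDFHEMTWSRDE
SFALHGCWSKWLPNQWYNCLFDIPCCNTVMRCISEDQFFILLCMGFCPVAYVMITFVGRG
>unrelated2
IHENFTSPVTANADKAICNQDNHWEPPCDIRKSITQAFIATGRPVQRSYQKKGSGANSFQ
IHYNYYQSYEEINHGCNKLMKKIFFVKNARMPVCTFCERWVQCDDQESTMWAYDSGKLMR
RATINQPYNQIWDYVQPEAQEFKDTDFTHIQRDQMNSELRNKLDFEKMHIIPYMLILHAW
WNDPRCFSLNGQVPTPAFVARINHFNRFTECIAKFDYNRDWDRMMPSHVLYMPFVQTIVE
>unrelated3
QREDCVYCSWVVDKMEIAGEKCMWIFYFFVVEIWGMWVESIVQADPPQPMNCKWCACLKL
NAMIQYWSVIVIWGTPGECSNSQRHWYQCTVVTYQIFHSNDDHAIAWGWARWFSTMARFQ
RQNRFPPASYKHPITGMDLGLWTAWRKRIHLAVEAIHTHKCDYKICTQVNHHPEVYWDAV
QLNTDHGRMWQHTFGHHRLPVGGCSHEMCQKVIYPFHTRCTKHPHKWRCEYLWRAKGPFN
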
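>SYN_PHNW synthetic stand-in marker (PhnW)
YWDDFPARNALEPHPLHHHWAVGCSAHEHGHNMGNNHREDPIITNECKRVLTFIMEIYCKVKRYGTAEYM
WMEESSMKRYFHEKWKNKHYHHFDRKFYRPVFIQKENRVDPTACYLLWDTPISNFKHYIMKWTDGQFEKR
GDYTWGDIMTRGHHSRDYFDHVDKIEEQDILYFSRTSQQWEMHQKLAFYQEGRQSPNWREEVQDEGCVIG
MKSEVDCLSMGIIIKLFQTLITMLPDRPCVGVDFAEQGDPATGLVVIRNNQTVKHELYDCCSEKIPCERQ
LGNRHRAMFTFNTCVHRYRWRSYLGCLLPKTSHYWHRPHQNQNNFVDWKFYVDVTMQNPFWPLEIFRMWL
KTWGFKWTTIKTLWD
>SYN_PHNX synthetic stand-in marker (PhnX)
RVKEKESVHGLMDVSLYCAWAHKYERPFLFVLASFQWPCSWQADDLFGPRCQFEQHITDGWGNTSVEANA
KCINDPMKVRGHISSVNRPRLHENVKQPYKQIFRLMAKKFARTFIKYVKLSHDVTFWYPPIMVLIKTRFE
LWIQKQMRFFIKWNRPQDAFSMKTMITRAFYFNIMGCWVAMVWWMTSKDMLLGPCGHMHEKMLIIQAREG
WTAFMEVWPWQVKATRVSPGRFVIDDMCSCAAIVYKPETDSWQEWFLNIAFNYDMDMSEK
>SYN_PHNY synthetic stand-in marker (PhnY)
RRGSGCLPFNSNQSNCGDMQYNYASYGDKPTPYMWYILQMYLNDIDRLGPQGQETHAKAIPHWWRKCYTK
EDHQESYVSMYYANWHHGTWPKFALFLYFCAMLCGGANCINIYQSHTLKTPMCVMSVKIIWRQEFRNIKQ
ILHNEEFNWAQMRLRYHSCSDLPVAWPEHWDKLDKDLNMMAELRIRFVDMFPVVISKWCILTFWMHQYFE
VLKAPIREWCNLQYVVYGCKDHTETHGFFNNANSEQHAKSTELSAAGTLGTRPLAPHWHESADEWSMTDT
EQDFQWTQIQTQHTESLLTQAPTSELQWECEKPLQGCTEQGVRTWAWGRFRIMFAEPEHNNYEFRATLFP
ALEYAVGNRLLVKQAELCVMPAPWCDAFVYMFDMHAPSYGQPPWDFYIPVCRFVHCMGTSQDWAPYKLCI
TFEIIRRCWPTIQHQCSKGQFDRLAMKIRMCHGEREKMEITHESLEFLLK
>SYN_PHNA synthetic stand-in marker (PhnA)
NSDHYCNVTGQSCIIPQTDKYGQMSQWFAAKMTNVVCYVCYIWDEDTYNATILQPIRAINAPCAGIMDED
KLNWICKCQQILSMNEITWYEFRIWFVNIWDDVYHMVHPQYTCILNFIINCTLLIVVPVNVRNFPVIEIN
WHSATHALYAEVFGMQQTNHYVTVQPMKELSCIGAFPVEVFKQDRCFITEHLSNMGWRRINAAWCAARYA
VSQQYCWCPQNWQEMFNAVMAMTLMDPDWFSGIYNNLWKQVADKDWEMSCHQHWWQLPQHCHIGFRGGCW
TMREARHWCQEKCWMCETGTCMGWMFMYHSKTWGHYIWMYACPPFNDMNVFMYELDGHTVRNWYWTIRIY
LQEGINAIAAKEISYGCTELSWMGSWMLFSEPKYKLRYALDRESICNFQT
>SYN_PBFA synthetic stand-in marker (PbfA)
NRLLPKHRHEYYGEKWFHADEIYQKKHDLFPFCCNYIPIRMFNTPLTQPHPFGNQCPNNSTFALFLQWYR
YSWQTINYGEDLANMNDAFYGNYVQQTMHHQKTIMDPIGFQECQSDNPACIEEFPRDFHTRCSYDTEKVR
AEPALKYNIFTFYLKIMKSHDICAMVEELAYRYADMCLANKTVHLQWNPKQNAVIHPDIIIGHCIQWTMY
NYDDSYKFQCLEHMYGWMDQKDQHDSLDVAQIRKSAFDAEVRHAIMPNHCRLGDEMGGWAKCSPRMFSDW
QMMDRRARCRMPPKAIDNYPMLEEEMAIPHARNRKPTKSFHYEPNDGPASSRELDDFERVQIHSDTHCGV
IREEMFDDSNFCPYKKTACNKADVLCYVKAIRPYQMVMYIFVAPLQPRAIFTAFAGEDIYGGQFKGSVFP
SPLTCLDDRSDRKNWRLSSA
>SYN_PBFC synthetic stand-in marker (PbfC)
LKEAWGAAQKFNTQTQREAGIPVKECGQLSRWGLIYQYCRSWSKEVKIIAAHEEIFHFIRNIFMMFRTMG
REAFKEDFQNGHHWFLDFLEDLTRRNNEKIDQQCGYSPGRNHTMANTTKCSQLKGTVIRHNGMHKFEDNY
ENWCVKANMADDRPSGQPTHQYEVWPLFTEQSWRHRLWIDFDKNQTSKVPLGPDFNFVNDGNHAGKICDG
KFWNADCHPCSNFFCQIQFKPNPKRKTGAFDVTCDKMDGHFIITLFHAYFRVHEPVDCRALRNCNERHKG
PDWQQSEKGLLCRYAKIVFDICCGDYSRIQKNRLFTVLAPHMPTEPEEWGQPCNHKIGESWMESECLPFF
IHQVMVAGYLWGIRAAPGDRNYILASHVWGGPEETYMHPWHKFHDDPHQNWCYYLEIMCGSIPTRCHVYG
YRSWVFVKSIDHHDTWTTCDKLVNCKWVCA
>SYN_PBFD synthetic stand-in marker (PbfD)
FFSLQYCHYHLAFHGYRGGFELMKVCNWAITKYKKYNVKMGCHDCPMKLGALSNFSLQILAIVQPNSLYH
CPQVYLMIYRARFQEQPCEHFSHMDTAVDCHLTLRSGRMLFLMSQYTIKKRAMSRDFFTYINRVFSRQHL
MYAMFQMGGHWWCYPIQMNMEPMFAIPTQREFQQLQKNDWSLTEDQTLWVAMQSVHYHMVAHENCNRINE
WTMKTGWPACNNNQSIHVEGCMVWAFCVHWWQQEFMLQYVEAKKTWMHFEYWRGGCDPHQNHRIINQKIF
YQLMCCDHKQLSGTKTHHPIILHRCFPGCCVHHLLKHRADRGWLFDPLMGLIASHGQGIFVHCWQYECIA
DCPHMARMQVTGYIPVIVCHGVKMAVHMEANPCPCLCVYNLALYDQYYVNCDRTYGSSYFLKHLENTRHK
PSECCIGLANADGYGQRRYAPSLLHPMWCQWQHMNDGPVWMCLCIMECAQVVSWLNKEFP
>SYN_PBFF synthetic stand-in marker (PbfF)
YNQTQQDFWSFCFITFFIHIERHPHEYFDWQDQGEGRFMLPFWQFQVQVCCWWMSSSKVHIGIFPSKGFL
RNCHEFKCPAIHGSNDLEYANFCNQNQDFWWQQTMKVDCQRRYQEAFDSSLEAIPQLREMLSCFVTDKYK
DNKTEHANSLWKKQFKSHAFTNWLIKYSSYWVLVWKYMGMPQRLVTDSRDSTPRSWWICAIKIQWYGNEF
GWLWLKWNKTFKMGYGEEYHQRQMEFKVHIIGMQITWIGLIDDMFIRCCVGWVLTHPDWWKNCRLPCTHT
YMGIWIMTCTIDERFAWDNIGYCYCEDPPHELFMLWNFEGIWKAEFCLARFMEVIPNIGI
>SYN_TRANSPORTER synthetic stand-in marker (transporter)
WRKNLGDKKDSGENFQRGVWTAIGEFRRSFAWRHHDYNLRHMLCAPATALFHPSMNHVSSPPPKFNDHWA
ENQFRYRTWDMYWQEPGTHMNNMKGHFWQTKENYPICWVHTDNQTWWLEQPKSKPPRPFHFWWRDWLTKG
PDKCKILHHHVSMSYNFWEFCDVCLADSATHTMIAPSIIMEHWTYECHVTGGNNEVCMKWNIGKWMHSNP
RPIRGHINYEFASGFLLWSQPKVRCEDWTDTKATWIMFWGMDRVCKCGGWQFSRRQVDIEHKKRAYHAHY
MRLTCRWWQMPTAYVFRHVR
>SYN_REGULATOR synthetic stand-in marker (regulator)
SSEGEKARMNNYNSYDKKFMAPWCDGLAYGDMWHFKTDCHTCGRFRCTPLQMLYTWQMNHCDGHEYWHCN
CHMHDVILRASEMGQGSGNCNHLALFLNFPAGYMSSIFYWKYCKSAVCFCLFIMTHTDAPWRVRAEYTKS
AGGVMEKKMTQADKRDTIIVYHRTGGSGFHYMCSQIETWNQTCHVRYNNWQCIDRNYRWNSENCSKHEGN
ECWHHAQCGTEWEGWFCWNY
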